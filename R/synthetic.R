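#' Configuration for the synthetic survey study
#'
#' Defines the conditions the generator emulates: three respondent surveys
#' (health, internal exposome, external exposome) with asymmetric completion
#' rates, binary / ordinal-frequency / free-text questions aligned to a
#' six-branch ontology, missing answers, and planted exposure-disorder
#' effects of known odds ratios. Default completion probabilities follow the
#' observed cohort asymmetry (health 0.965, internal 0.311, external 0.367);
#' the default planted effects attach odds ratios 3.0, 2.0 and 0.4 to the
#' three reproductive disorders.
#'
#' @param n_respondents Number of survey respondents.
#' @param survey_completion_probs Named probabilities (health, internal,
#'   external) that a respondent completes each survey, independently.
#' @param n_ontology_terms Named counts of terms per ontology branch.
#' @param n_questions Named question counts per survey.
#' @param planted_effects `NULL` for the defaults, or a data.frame with
#'   columns `disorder` (CURIE), `exposure` (CURIE), `odds_ratio`,
#'   `exposure_prevalence`.
#' @param baseline_prevalence Marginal prevalence targeted for each disorder
#'   (the logistic intercept is solved so the population marginal matches).
#' @param missing_rate Probability that an answer within a completed survey
#'   is missing (MCAR by default).
#' @param mar If `TRUE`, missingness of non-health answers depends on the
#'   respondent's first health answer (a simple MAR mechanism to stress the
#'   imputer).
#' @param prop_female Proportion of female respondents.
#' @param typo_rate Probability a free-text answer carries a typographical
#'   error (so it lands in the unmapped-response report).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_respondents = 2000,
                         survey_completion_probs = c(health = 0.965,
                                                     internal = 0.311,
                                                     external = 0.367),
                         n_ontology_terms = c(disease = 50, phenotype = 50,
                                              food = 50, chemical = 50,
                                              exposure = 50,
                                              medical_action = 50),
                         n_questions = c(health = 14, internal = 12,
                                         external = 8),
                         planted_effects = NULL,
                         baseline_prevalence = 0.1,
                         missing_rate = 0.05,
                         mar = FALSE,
                         prop_female = 0.67,
                         typo_rate = 0.05,
                         seed = 1L) {
  probs <- c(survey_completion_probs, baseline_prevalence, missing_rate,
             prop_female, typo_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (!is.null(planted_effects)) {
    stopifnot(all(c("disorder", "exposure", "odds_ratio",
                    "exposure_prevalence") %in% names(planted_effects)))
    if (any(planted_effects$odds_ratio <= 0)) stop("odds ratios must be > 0")
    if (any(planted_effects$exposure_prevalence < 0 |
            planted_effects$exposure_prevalence > 1)) {
      stop("exposure prevalences must be in [0, 1]")
    }
  }
  structure(list(
    n_respondents = as.integer(n_respondents),
    survey_completion_probs = survey_completion_probs,
    n_ontology_terms = n_ontology_terms,
    n_questions = n_questions,
    planted_effects = planted_effects,
    baseline_prevalence = baseline_prevalence,
    missing_rate = missing_rate,
    mar = isTRUE(mar),
    prop_female = prop_female,
    typo_rate = typo_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Solve the logistic intercept so the marginal disorder prevalence equals the
# target, by bisection over the exact mixture across independent exposures.
solve_intercept <- function(log_ors, prevalences, target) {
  k <- length(log_ors)
  if (k == 0) return(stats::qlogis(target))
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  w <- apply(combos, 1, function(x) prod(ifelse(x == 1, prevalences, 1 - prevalences)))
  lin <- as.numeric(combos %*% log_ors)
  marginal <- function(b0) sum(w * stats::plogis(b0 + lin)) - target
  stats::uniroot(marginal, lower = -30, upper = 30, tol = 1e-10)$root
}

# Build the survey schema: questions plus their translation-key rows.
build_schema <- function(config, onto) {
  nq <- config$n_questions
  frds <- attr(onto, "frd_curies")
  pick <- function(branch, n, exclude = character(0)) {
    ids <- onto$nodes$id[onto$nodes$category == branch]
    ids <- setdiff(ids[-1], exclude)  # skip branch roots
    if (length(ids) < n) stop("not enough ", branch, " terms for the requested questions")
    sample(ids, n)
  }
  # Health survey: the FRD questions first, then other diseases, phenotypes
  # and medical actions, all binary.
  n_h <- nq[["health"]]
  if (n_h < length(frds) + 3) stop("health survey needs at least 6 questions")
  n_rest <- n_h - length(frds)
  n_dis <- floor(n_rest / 3); n_phe <- floor(n_rest / 3)
  n_act <- n_rest - n_dis - n_phe
  h_curies <- c(frds,
                pick("disease", n_dis, exclude = frds),
                pick("phenotype", n_phe),
                pick("medical_action", n_act))
  h_pred <- c(rep("has_disease", length(frds) + n_dis),
              rep("has_phenotype", n_phe),
              rep("undergone", n_act))
  # Internal survey: ordinal food-frequency questions plus free-text
  # medication questions (each probing one chemical).
  n_i <- nq[["internal"]]
  n_ft <- max(2L, round(n_i / 5))
  n_food <- n_i - n_ft
  i_food <- pick("food", n_food)
  i_chem <- pick("chemical", n_ft)
  # External survey: binary environmental-exposure questions.
  n_e <- nq[["external"]]
  e_curies <- pick("exposure", n_e)

  questions <- rbind(
    data.frame(question_id = sprintf("H%02d", seq_len(n_h)), survey = "health",
               response_type = "binary", topic = "health condition",
               curie = h_curies, predicate = h_pred, stringsAsFactors = FALSE),
    data.frame(question_id = sprintf("I%02d", seq_len(n_food)),
               survey = "internal", response_type = "ordinal_frequency",
               topic = "food frequency", curie = i_food,
               predicate = "consumes", stringsAsFactors = FALSE),
    data.frame(question_id = sprintf("I%02d", n_food + seq_len(n_ft)),
               survey = "internal", response_type = "free_text",
               topic = "medication", curie = i_chem,
               predicate = "affected_by", stringsAsFactors = FALSE),
    data.frame(question_id = sprintf("E%02d", seq_len(n_e)),
               survey = "external", response_type = "binary",
               topic = "environmental exposure", curie = e_curies,
               predicate = "exposed_to", stringsAsFactors = FALSE)
  )
  rownames(questions) <- NULL
  questions
}

default_effects <- function(questions, frds) {
  ord <- questions$curie[questions$response_type == "ordinal_frequency"]
  exp_q <- questions$curie[questions$survey == "external"]
  if (length(frds) < 3 || length(ord) < 2 || length(exp_q) < 1) {
    stop("default planted effects need 3 FRDs, 2 food questions and 1 exposure question")
  }
  data.frame(
    disorder = unname(frds[1:3]),
    exposure = c(ord[1], exp_q[1], ord[2]),
    odds_ratio = c(3.0, 2.0, 0.4),
    exposure_prevalence = c(0.30, 0.25, 0.40),
    stringsAsFactors = FALSE
  )
}

add_typo <- function(s) {
  chars <- strsplit(s, "")[[1]]
  i <- sample.int(length(chars), 1)
  chars[i] <- sample(letters, 1)
  paste(chars, collapse = "")
}

#' Generate a synthetic respondent population
#'
#' Draws exposure indicators Bernoulli(prevalence), disorder status from an
#' additive-logit model `logit(P) = b0 + sum(log(OR_k) * exposure_k)` with
#' the intercept solved by bisection so the marginal prevalence matches
#' `baseline_prevalence`, survey completion per respondent, and missingness
#' within completed surveys. Ordinal food-frequency answers use a 0-5 scale;
#' free-text medication answers emit the chemical's label or its registered
#' brand-name synonym, with occasional typographical noise.
#'
#' @param config A [synth_config()].
#' @param ontology The [generate_ontology()] output for the same config.
#' @return A `synthetic_bundle`: list with `ontology`, `questions`,
#'   `translation_key`, `respondents`, `responses`, `supplemental_links`,
#'   `truth` (the planted effects), and `config`.
#' @export
generate_population <- function(config, ontology) {
  stopifnot(inherits(config, "synth_config"), inherits(ontology, "ontology"))
  set.seed(config$seed + 1L)
  questions <- build_schema(config, ontology)
  frds <- attr(ontology, "frd_curies")
  effects <- config$planted_effects
  if (is.null(effects)) effects <- default_effects(questions, frds)
  known <- unique(questions$curie)
  bad <- setdiff(c(effects$exposure, effects$disorder),
                 c(known, unname(frds)))
  if (length(bad) > 0) {
    stop("planted effects reference CURIEs not reachable from any question: ",
         paste(bad, collapse = ", "))
  }

  n <- config$n_respondents
  ids <- sprintf("P%05d", seq_len(n))
  respondents <- data.frame(
    respondent_id = ids,
    gender = ifelse(stats::runif(n) < config$prop_female, "female", "male"),
    completed_health = stats::runif(n) < config$survey_completion_probs[["health"]],
    completed_internal = stats::runif(n) < config$survey_completion_probs[["internal"]],
    completed_external = stats::runif(n) < config$survey_completion_probs[["external"]],
    stringsAsFactors = FALSE
  )

  # Latent exposure indicators for every planted exposure CURIE.
  exp_curies <- unique(effects$exposure)
  exp_prev <- vapply(exp_curies, function(cu) {
    effects$exposure_prevalence[match(cu, effects$exposure)]
  }, numeric(1))
  exposure_ind <- matrix(0L, n, length(exp_curies),
                         dimnames = list(NULL, exp_curies))
  for (j in seq_along(exp_curies)) {
    exposure_ind[, j] <- as.integer(stats::runif(n) < exp_prev[j])
  }

  # Disorder status from the additive-logit model.
  disorder_curies <- unique(c(unname(frds), effects$disorder))
  disorder_status <- matrix(0L, n, length(disorder_curies),
                            dimnames = list(NULL, disorder_curies))
  for (d in disorder_curies) {
    eff <- effects[effects$disorder == d, , drop = FALSE]
    b0 <- solve_intercept(log(eff$odds_ratio), eff$exposure_prevalence,
                          config$baseline_prevalence)
    lin <- b0
    if (nrow(eff) > 0) {
      lin <- lin + as.numeric(exposure_ind[, eff$exposure, drop = FALSE] %*%
                                log(eff$odds_ratio))
    }
    disorder_status[, d] <- as.integer(stats::runif(n) < stats::plogis(lin))
  }

  # Per-question background parameters (fixed once, seed-determined).
  qn <- questions
  bg_yes <- stats::runif(nrow(qn), 0.05, 0.5)
  bg_zero <- stats::runif(nrow(qn), 0.2, 0.6)
  use_prev <- stats::runif(nrow(qn), 0.05, 0.3)

  chem_nodes <- ontology$nodes[match(qn$curie, ontology$nodes$id), ]
  surveys <- qn$survey
  completed <- cbind(health = respondents$completed_health,
                     internal = respondents$completed_internal,
                     external = respondents$completed_external)

  res_list <- vector("list", nrow(qn))
  for (q in seq_len(nrow(qn))) {
    cu <- qn$curie[q]
    type <- qn$response_type[q]
    planted <- cu %in% exp_curies
    if (type == "binary") {
      if (cu %in% disorder_curies) {
        yes <- disorder_status[, cu] == 1L
      } else if (planted) {
        yes <- exposure_ind[, cu] == 1L
      } else {
        yes <- stats::runif(n) < bg_yes[q]
      }
      value <- ifelse(yes, "yes", "no")
    } else if (type == "ordinal_frequency") {
      if (planted) {
        consumed <- exposure_ind[, cu] == 1L
      } else {
        consumed <- stats::runif(n) >= bg_zero[q]
      }
      value <- integer(n)
      value[consumed] <- sample(1:5, sum(consumed), replace = TRUE)
      value <- as.character(value)
    } else { # free_text
      used <- if (planted) exposure_ind[, cu] == 1L else stats::runif(n) < use_prev[q]
      label <- chem_nodes$name[q]
      synonym <- chem_nodes$synonyms[q]
      txt <- rep("none", n)
      if (any(used)) {
        use_syn <- nzchar(synonym) & stats::runif(n) < 0.5
        txt[used] <- ifelse(use_syn[used], synonym, label)
        typo <- used & stats::runif(n) < config$typo_rate
        txt[typo] <- vapply(txt[typo], add_typo, character(1))
      }
      value <- txt
    }
    keep <- completed[, surveys[q]]
    res_list[[q]] <- data.frame(
      respondent_id = ids[keep], survey = surveys[q],
      question_id = qn$question_id[q], value = value[keep],
      stringsAsFactors = FALSE
    )
  }
  responses <- do.call(rbind, res_list)
  rownames(responses) <- NULL

  # Missingness within completed surveys: MCAR, or MAR driven by the first
  # health answer when requested.
  if (config$missing_rate > 0) {
    if (config$mar) {
      h1 <- responses$value[responses$question_id == "H01"]
      names(h1) <- responses$respondent_id[responses$question_id == "H01"]
      shift <- ifelse(!is.na(h1[responses$respondent_id]) &
                        h1[responses$respondent_id] == "yes", 2, 0.5)
      shift[is.na(shift)] <- 1
      p_miss <- pmin(1, config$missing_rate * shift)
      p_miss[responses$question_id == "H01"] <- config$missing_rate
    } else {
      p_miss <- config$missing_rate
    }
    miss <- stats::runif(nrow(responses)) < p_miss
    responses$value[miss] <- NA_character_
  }

  # Supplemental food -> chemical/nutrient links: some for question-mapped
  # foods, some deliberately for unmapped foods (the graph builder must drop
  # those).
  food_all <- ontology$nodes$id[ontology$nodes$category == "food"][-1]
  chem_all <- ontology$nodes$id[ontology$nodes$category == "chemical"][-1]
  food_q <- qn$curie[qn$response_type == "ordinal_frequency"]
  supp_subjects <- c(food_q, utils::head(setdiff(food_all, food_q), 5))
  supp <- do.call(rbind, lapply(supp_subjects, function(f) {
    rows <- list()
    if (stats::runif(1) < 0.6) {
      rows[[1]] <- data.frame(subject = f, predicate = "applied_with",
                              object = sample(chem_all, 1),
                              stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.6) {
      rows[[2]] <- data.frame(subject = f, predicate = "contains_nutrient",
                              object = sample(chem_all, 1),
                              stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  if (is.null(supp)) {
    supp <- data.frame(subject = character(), predicate = character(),
                       object = character(), stringsAsFactors = FALSE)
  }
  rownames(supp) <- NULL

  key <- data.frame(
    question_id = qn$question_id,
    response_type = qn$response_type,
    predicate = qn$predicate,
    curie_or_map = ifelse(qn$response_type == "free_text", "MATCH", qn$curie),
    stringsAsFactors = FALSE
  )

  structure(list(
    ontology = ontology, questions = qn, translation_key = key,
    respondents = respondents, responses = responses,
    supplemental_links = supp, truth = effects, config = config
  ), class = "synthetic_bundle")
}

#' Generate a full synthetic bundle in one call
#'
#' @param config A [synth_config()].
#' @return A `synthetic_bundle` (see [generate_population()]).
#' @export
generate_bundle <- function(config = synth_config()) {
  onto <- generate_ontology(config)
  generate_population(config, onto)
}

#' The standard synthetic bundle used for skill and recovery checks
#'
#' n = 2000 respondents, a six-branch ontology of about 300 terms, and the
#' three default planted effects (odds ratios 3.0, 2.0 and 0.4). Survey
#' completion is set to 1 and missingness to 0.02 so the nominal sample size
#' is the effective one for both analysis arms; survey-completion attrition
#' is a separate mechanism exercised by the cohort-cleaning tests and the
#' workflow scenario.
#'
#' @param seed Integer seed.
#' @return A `synthetic_bundle`.
#' @export
standard_bundle <- function(seed = 1L) {
  generate_bundle(synth_config(
    n_respondents = 2000,
    survey_completion_probs = c(health = 1, internal = 1, external = 1),
    missing_rate = 0.02,
    seed = seed
  ))
}

#' Write a synthetic bundle to TSV files
#'
#' Ontology nodes/edges in the KGX dialect (`id,category,name` /
#' `subject,predicate,object`), responses in long format, plus questions,
#' translation key, respondents, supplemental links and the planted-effect
#' truth table.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    path
  }
  files <- c(
    wt(bundle$ontology$nodes[, c("id", "category", "name", "synonyms")],
       "ontology_nodes.tsv"),
    wt(bundle$ontology$edges, "ontology_edges.tsv"),
    wt(bundle$questions, "questions.tsv"),
    wt(bundle$translation_key, "translation_key.tsv"),
    wt(bundle$respondents, "respondents.tsv"),
    wt(bundle$responses, "responses.tsv"),
    wt(bundle$supplemental_links, "supplemental_links.tsv"),
    wt(bundle$truth, "truth.tsv")
  )
  invisible(files)
}
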