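#' Clean the cohort for the regression arm
#'
#' Restricts rows to female respondents who completed all three surveys and
#' features to the ontology-aligned question set, and builds the wide
#' feature table keyed by CURIE: binary answers coded 0/1, ordinal
#' food-frequency answers kept at full 0-5 resolution (they are binarized
#' only in the graph arm), free-text medication mentions resolved through
#' the lexical matcher to a 0/1 indicator. Missing answers stay `NA`
#' (the missingness mask). Multiple questions mapping to one CURIE collapse
#' by maximum.
#'
#' @param respondents data.frame with `respondent_id`, `gender` and
#'   `completed_health` / `completed_internal` / `completed_external` flags.
#' @param responses Long response data.frame.
#' @param questions Question schema (`question_id, survey, response_type,
#'   curie`).
#' @param ontology An [ontology()] (for free-text matching).
#' @return data.frame of class `feature_table`: `respondent_id` plus one
#'   numeric column per CURIE, with attributes `feature_types` and
#'   `raw` (identical copy, kept for pre-imputation prevalence statistics).
#' @export
clean_cohort <- function(respondents, responses, questions, ontology) {
  fem <- respondents[respondents$gender == "female", , drop = FALSE]
  if (nrow(fem) == 0) stop("empty cohort after the female-only filter")
  keep <- fem$completed_health & fem$completed_internal & fem$completed_external
  cohort <- fem[keep, , drop = FALSE]
  if (nrow(cohort) == 0) {
    stop("empty cohort after the all-three-surveys completion filter")
  }
  ids <- cohort$respondent_id
  res <- responses[responses$respondent_id %in% ids, , drop = FALSE]
  attr(ontology, ".lex_index") <- lexical_index(ontology)

  curies <- unique(questions$curie)
  tab <- matrix(NA_real_, nrow = length(ids), ncol = length(curies),
                dimnames = list(ids, curies))
  types <- stats::setNames(rep("binary", length(curies)), curies)
  for (q in seq_len(nrow(questions))) {
    qid <- questions$question_id[q]
    cu <- questions$curie[q]
    ty <- questions$response_type[q]
    rr <- res[res$question_id == qid, , drop = FALSE]
    if (nrow(rr) == 0) next
    v <- rr$value
    coded <- switch(ty,
      binary = ifelse(is.na(v), NA_real_, as.numeric(affirmative(v))),
      ordinal_frequency = suppressWarnings(as.numeric(v)),
      free_text = {
        out <- rep(0, length(v))
        out[is.na(v)] <- NA_real_
        txt <- !is.na(v) & nzchar(v) & normalize_text(v) != "none"
        if (any(txt)) {
          hit <- match_free_text(v[txt], ontology)
          out[txt] <- as.numeric(!is.na(hit) & hit == cu)
        }
        out
      },
      stop("unsupported response type in cohort cleaning: ", ty))
    if (ty == "ordinal_frequency") types[cu] <- "ordinal"
    ri <- match(rr$respondent_id, ids)
    cur <- tab[cbind(ri, match(cu, curies))]
    tab[cbind(ri, match(cu, curies))] <- pmax(cur, coded, na.rm = TRUE)
  }
  df <- data.frame(respondent_id = ids, tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, feature_types = types, raw = df,
            class = c("feature_table", "data.frame"))
}

feature_columns <- function(table) setdiff(names(table), "respondent_id")

#' Iterative random-forest imputation
#'
#' Implements the missForest scheme: missing cells are initialized with the
#' column mean (ordinal/continuous) or mode (binary); columns are visited in
#' order of increasing missingness, each fitted by a random forest on the
#' currently completed other columns using its observed rows and predicted
#' on its missing rows; sweeps stop when the imputation-difference statistic
#' increases (computed separately for the continuous and categorical parts)
#' or `max_iter` is reached, and the last table before degradation is
#' returned. Observed cells are never altered. Fully missing columns are
#' dropped with a warning.
#'
#' @param table A `feature_table` (or plain data.frame with
#'   `respondent_id`).
#' @param max_iter Maximum sweeps.
#' @param n_trees Trees per column forest.
#' @param seed Integer seed.
#' @return The imputed table (same class/attributes), attribute
#'   `n_iterations` recording the sweeps performed.
#' @export
impute_missforest <- function(table, max_iter = 10, n_trees = 100, seed = 1L) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    warning("dropping fully missing columns: ",
            paste(feats[all_na], collapse = ", "))
    X <- X[, !all_na, drop = FALSE]
    feats <- feats[!all_na]
  }
  miss <- is.na(X)
  if (!any(miss)) {
    out <- table
    attr(out, "n_iterations") <- 0L
    return(out)
  }
  types <- attr(table, "feature_types")
  if (is.null(types)) {
    types <- vapply(feats, function(f) {
      obs <- X[!miss[, f], f]
      if (all(obs %in% c(0, 1))) "binary" else "ordinal"
    }, character(1))
  }
  is_cat <- types[feats] == "binary"

  mode_of <- function(v) as.numeric(names(which.max(base::table(v))))
  for (j in seq_along(feats)) {
    obs <- X[!miss[, j], j]
    fill <- if (is_cat[j]) mode_of(obs) else mean(obs)
    X[miss[, j], j] <- fill
  }

  ord <- order(colSums(miss))
  set.seed(seed)
  prev_diff_cont <- Inf
  prev_diff_cat <- Inf
  X_best <- X
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    X_old <- X
    for (j in ord) {
      mj <- miss[, j]
      if (!any(mj)) next
      d <- data.frame(X[, -j, drop = FALSE])
      names(d) <- paste0("x", seq_len(ncol(d)))
      if (is_cat[j]) {
        y <- factor(X[!mj, j])
        if (nlevels(y) < 2) { X[mj, j] <- as.numeric(as.character(y[1])); next }
        fit <- ranger::ranger(x = d[!mj, , drop = FALSE], y = y,
                              num.trees = n_trees, num.threads = 1,
                              seed = seed + iter * 1000L + j)
        pred <- stats::predict(fit, data = d[mj, , drop = FALSE],
                               num.threads = 1)$predictions
        X[mj, j] <- as.numeric(as.character(pred))
      } else {
        fit <- ranger::ranger(x = d[!mj, , drop = FALSE], y = X[!mj, j],
                              num.trees = n_trees, num.threads = 1,
                              seed = seed + iter * 1000L + j)
        X[mj, j] <- stats::predict(fit, data = d[mj, , drop = FALSE],
                                   num.threads = 1)$predictions
      }
    }
    cont <- !is_cat
    diff_cont <- if (any(cont)) {
      denom <- sum(X[, cont]^2)
      if (denom == 0) 0 else sum((X[, cont] - X_old[, cont])^2) / denom
    } else NA_real_
    diff_cat <- if (any(is_cat)) {
      n_na_cat <- sum(miss[, is_cat])
      if (n_na_cat == 0) 0 else
        sum(X[, is_cat][miss[, is_cat]] != X_old[, is_cat][miss[, is_cat]]) / n_na_cat
    } else NA_real_
    worse_cont <- !is.na(diff_cont) && diff_cont > prev_diff_cont
    worse_cat <- !is.na(diff_cat) && diff_cat > prev_diff_cat
    both_types <- !is.na(diff_cont) && !is.na(diff_cat)
    stop_now <- if (both_types) worse_cont && worse_cat else (worse_cont || worse_cat)
    if (stop_now) {
      X <- X_best
      iter <- iter - 1L
      break
    }
    X_best <- X
    prev_diff_cont <- if (!is.na(diff_cont)) diff_cont else prev_diff_cont
    prev_diff_cat <- if (!is.na(diff_cat)) diff_cat else prev_diff_cat
    if ((is.na(diff_cont) || diff_cont == 0) &&
        (is.na(diff_cat) || diff_cat == 0)) break
  }
  out <- table
  for (f in feats) out[[f]] <- X_best[, f]
  dropped <- setdiff(feature_columns(table), feats)
  if (length(dropped) > 0) out[dropped] <- NULL
  attr(out, "n_iterations") <- iter
  attr(out, "feature_types") <- types
  out
}

#' Two-stage supervised feature selection
#'
#' Stage 1: elastic-net-penalized logistic regression (mixing parameter 0.5,
#' penalty chosen by seeded 5-fold cross-validation) retains features with
#' nonzero coefficients. Stage 2: a class-weight-balanced random forest is
#' fit on the retained features on two thirds of the rows; permutation
#' importance (default 20 seeded permutations per feature, AUROC drop on the
#' held-out third) ranks them, and features with positive importance are
#' returned.
#'
#' @param table Imputed `feature_table`.
#' @param outcome Outcome CURIE (binary column of `table`).
#' @param seed Integer seed.
#' @param n_permutations Permutations per feature.
#' @param exclude Feature columns to leave out (besides the outcome).
#' @param elastic_net If `FALSE`, stage 1 is a univariate-filter selector
#'   (per-feature logistic Wald p < 0.1) instead of the elastic net.
#' @return data.frame `feature, importance`, ranked by decreasing
#'   importance; zero rows when nothing survives.
#' @export
select_features <- function(table, outcome, seed = 1L, n_permutations = 20,
                            exclude = character(0), elastic_net = TRUE) {
  feats <- setdiff(feature_columns(table), c(outcome, exclude))
  if (length(feats) < 2) stop("need at least two candidate features")
  y <- table[[outcome]]
  if (length(unique(y)) < 2) stop("outcome has a single class")
  X <- as.matrix(table[, feats, drop = FALSE])
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  feats <- feats[keep]

  set.seed(seed)
  if (elastic_net) {
    foldid <- sample(rep_len(1:5, length(y)))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0.5,
                            foldid = foldid)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    retained <- feats[beta != 0]
  } else {
    p1 <- vapply(seq_along(feats), function(j) {
      f <- stats::glm(y ~ X[, j], family = stats::binomial())
      stats::coef(summary(f))[2, 4]
    }, numeric(1))
    retained <- feats[p1 < 0.1]
  }
  if (length(retained) == 0) {
    warning("no features retained by the stage-1 selector")
    return(data.frame(feature = character(), importance = numeric(),
                      stringsAsFactors = FALSE))
  }

  n <- length(y)
  hold <- sample.int(n, floor(n / 3))
  if (length(unique(y[hold])) < 2 || length(unique(y[-hold])) < 2) {
    # degenerate split under extreme imbalance: stratify
    pos <- which(y == max(y)); negi <- which(y == min(y))
    hold <- c(sample(pos, max(1, floor(length(pos) / 3))),
              sample(negi, max(1, floor(length(negi) / 3))))
  }
  dtr <- data.frame(X[-hold, retained, drop = FALSE], check.names = FALSE)
  names(dtr) <- paste0("x", seq_along(retained))
  ytr <- factor(y[-hold], levels = sort(unique(y)))
  cw <- as.numeric(1 / base::table(ytr)); cw <- cw / sum(cw)
  rf <- ranger::ranger(x = dtr, y = ytr, probability = TRUE,
                       num.trees = 200, class.weights = cw,
                       seed = seed, num.threads = 1)
  dho <- data.frame(X[hold, retained, drop = FALSE], check.names = FALSE)
  names(dho) <- names(dtr)
  yho <- y[hold]
  pos_level <- as.character(max(y))
  score <- function(d) {
    p <- stats::predict(rf, data = d, num.threads = 1)$predictions[, pos_level]
    auroc(p[yho == max(y)], p[yho == min(y)])
  }
  base <- score(dho)
  imp <- vapply(seq_along(retained), function(j) {
    drops <- vapply(seq_len(n_permutations), function(r) {
      dp <- dho
      dp[[j]] <- sample(dp[[j]])
      base - score(dp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = retained, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[out$importance > 0, , drop = FALSE]
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni family-wise adjustment
#'
#' `p_adj = min(1, m * p)`, order preserved.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param m Family size (defaults to `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, m * pvals)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing feature j on the remaining
#' features. Non-computable cases (singular design, perfect collinearity)
#' are returned as `NA`, the "inadequate information" convention.
#'
#' @param table Feature table (imputed).
#' @param features Feature columns to diagnose.
#' @return Named numeric vector of VIFs (`NA` where not computable).
#' @export
compute_vif <- function(table, features) {
  if (length(features) < 2) {
    return(stats::setNames(rep(NA_real_, length(features)), features))
  }
  X <- as.matrix(table[, features, drop = FALSE])
  vif <- vapply(seq_along(features), function(j) {
    yj <- X[, j]
    Zj <- X[, -j, drop = FALSE]
    if (stats::sd(yj) == 0) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, Zj), yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    if (r2 > 1 - 1e-10) NA_real_ else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(vif, features)
}

#' Multivariable logistic regression with odds-ratio reporting
#'
#' Maximum-likelihood joint fit of the outcome on the selected features.
#' Per-feature odds ratio `exp(b)`, 95% CI `exp(b +/- 1.96 SE)`, Wald
#' p-values, Bonferroni-adjusted p-values (family size = number of tested
#' features), pre-imputation prevalence and missingness statistics, and
#' per-feature VIF. Features flagged by (quasi-)complete separation are kept
#' with unbounded confidence intervals rather than dropped.
#'
#' @param table Imputed `feature_table`.
#' @param outcome Outcome CURIE.
#' @param features Character vector of selected feature CURIEs.
#' @param raw_table Pre-imputation table for prevalence/missingness stats
#'   (defaults to `attr(table, "raw")`).
#' @param labels Optional named vector CURIE -> display label.
#' @return data.frame of class `regression_result` with the reporting
#'   schema columns.
#' @export
fit_logistic <- function(table, outcome, features, raw_table = NULL,
                         labels = NULL) {
  if (length(features) == 0) stop("no features to fit")
  if (nrow(table) <= length(features)) {
    stop("need more observations than features")
  }
  if (is.null(raw_table)) raw_table <- attr(table, "raw")
  d <- data.frame(as.matrix(table[, features, drop = FALSE]),
                  check.names = FALSE)
  names(d) <- paste0("x", seq_along(features))
  d$y <- table[[outcome]]
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(summary(fit))
  rows <- match(paste0("x", seq_along(features)), rownames(cf))
  b <- cf[rows, 1]
  se <- cf[rows, 2]
  p <- cf[rows, 4]
  # aliased (perfectly collinear) features are reported with NA estimates
  separated <- !is.na(se) & ((sep_warn & (abs(b) > 10 | se > 10)) | se > 100)
  ci_low <- exp(b - 1.96 * se)
  ci_high <- exp(b + 1.96 * se)
  ci_low[separated] <- 0
  ci_high[separated] <- Inf

  raw <- if (!is.null(raw_table)) raw_table else table
  prev_mean <- vapply(features, function(f) mean(raw[[f]], na.rm = TRUE), numeric(1))
  prev_sd <- vapply(features, function(f) stats::sd(raw[[f]], na.rm = TRUE), numeric(1))
  miss_rate <- vapply(features, function(f) mean(is.na(raw[[f]])), numeric(1))
  vif <- compute_vif(table, features)

  out <- data.frame(
    feature = features,
    label = if (is.null(labels)) features else unname(labels[features]),
    odds_ratio = exp(b),
    ci_low = ci_low,
    ci_high = ci_high,
    standard_error = se,
    p_raw = p,
    p_adjusted = {
      padj <- rep(NA_real_, length(p))
      ok <- !is.na(p)
      padj[ok] <- bonferroni_adjust(p[ok], m = length(features))
      padj
    },
    mean_prevalence = prev_mean,
    sd_prevalence = prev_sd,
    missingness_rate = miss_rate,
    mean_vif = unname(vif),
    separated = separated,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("regression_result", "data.frame"),
            outcome = outcome)
}

#' Run the full regression arm on a synthetic bundle
#'
#' Cohort cleaning, iterative RF imputation, per-disorder feature selection
#' and multivariable logistic regression with Bonferroni adjustment.
#'
#' @param bundle A `synthetic_bundle`.
#' @param seed Integer seed.
#' @param select If `FALSE`, skip feature selection and fit all features.
#' @param impute_trees,impute_max_iter Imputer settings.
#' @return List with `results` (one `regression_result` per FRD, named by
#'   disorder CURIE), `table` (imputed), `raw` (pre-imputation).
#' @export
run_regression_arm <- function(bundle, seed = 1L, select = TRUE,
                               impute_trees = 100, impute_max_iter = 10) {
  tab <- clean_cohort(bundle$respondents, bundle$responses, bundle$questions,
                      bundle$ontology)
  raw <- attr(tab, "raw")
  imp <- impute_missforest(tab, max_iter = impute_max_iter,
                           n_trees = impute_trees, seed = seed)
  frds <- attr(bundle$ontology, "frd_curies")
  frds <- frds[frds %in% names(imp)]
  labels <- stats::setNames(bundle$ontology$nodes$name, bundle$ontology$nodes$id)
  results <- lapply(frds, function(d) {
    feats <- if (select) {
      sel <- select_features(imp, d, seed = seed)
      sel$feature
    } else {
      setdiff(feature_columns(imp), d)
    }
    if (length(feats) == 0) return(NULL)
    fit_logistic(imp, d, feats, raw_table = raw, labels = labels)
  })
  names(results) <- frds
  list(results = results, table = imp, raw = raw)
}
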