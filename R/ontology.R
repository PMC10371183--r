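#' Ontology container
#'
#' A minimal in-memory representation of a merged biomedical ontology:
#' CURIE-identified terms with labels and optional synonyms, plus `is_a`
#' (subclass) edges forming a rooted DAG per branch.
#'
#' @param nodes data.frame with columns `id` (CURIE), `category`, `name`,
#'   `synonyms` (pipe-separated string, may be empty).
#' @param edges data.frame with columns `subject`, `predicate`, `object`;
#'   subclass edges point child -> parent with predicate `"subclass_of"`.
#' @return An object of class `ontology`.
#' @export
ontology <- function(nodes, edges) {
  stopifnot(all(c("id", "category", "name") %in% names(nodes)))
  if (is.null(nodes$synonyms)) nodes$synonyms <- ""
  nodes$synonyms[is.na(nodes$synonyms)] <- ""
  if (nrow(edges) > 0) {
    stopifnot(all(c("subject", "predicate", "object") %in% names(edges)))
    bad <- setdiff(c(edges$subject, edges$object), nodes$id)
    if (length(bad) > 0) {
      stop("ontology edges reference unknown terms: ", paste(bad, collapse = ", "))
    }
  } else {
    edges <- data.frame(subject = character(), predicate = character(),
                        object = character(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(nodes$id)) stop("duplicate CURIEs in ontology nodes")
  structure(list(nodes = nodes, edges = edges), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d subclass edges, %d branches\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$category))))
  invisible(x)
}

#' Test whether CURIEs resolve in an ontology
#'
#' @param ontology An [ontology()] object.
#' @param curies Character vector of CURIEs.
#' @return Logical vector.
#' @export
ontology_contains <- function(ontology, curies) {
  curies %in% ontology$nodes$id
}

# Branch metadata shared by the generator and the graph builder.
branch_prefixes <- c(
  disease = "MONDO", phenotype = "HP", food = "FOODON",
  chemical = "CHEBI", exposure = "ECTO", medical_action = "MAXO"
)

curie_for <- function(branch, local) {
  sprintf("%s:%07d", branch_prefixes[[branch]], local)
}

#' Generate a synthetic multi-branch ontology
#'
#' Builds one rooted DAG per branch (disease, phenotype, food, chemical,
#' exposure, medical action). Every non-root term receives one `is_a` parent
#' drawn uniformly from earlier terms in its branch and, with probability
#' 0.2, a second distinct parent, so branches are DAGs by construction.
#' Chemical terms carry one synthetic brand-name synonym to exercise
#' synonym-based lexical matching. The first three disease terms after the
#' root are the female reproductive disorders (FRDs) under study:
#' endometriosis, uterine fibroids, and ovarian cysts.
#'
#' @param config A [synth_config()] object.
#' @return An [ontology()] with attribute `frd_curies`.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nt <- config$n_ontology_terms
  if (any(nt < 1)) stop("configuration error: n_ontology_terms must be >= 1 per branch")
  set.seed(config$seed)
  frd_names <- c("endometriosis", "uterine fibroids", "ovarian cysts")
  nodes <- list(); edges <- list()
  for (branch in names(branch_prefixes)) {
    n <- nt[[branch]]
    ids <- vapply(seq_len(n), function(i) curie_for(branch, i), character(1))
    names_b <- c(paste(branch, "root"),
                 if (n > 1) paste(branch, "term", seq(2, n)))
    syn <- rep("", n)
    if (branch == "chemical") {
      syn <- paste0("Brand", sprintf("%07d", seq_len(n)))
      syn[1] <- ""
    }
    if (branch == "disease" && n >= 4) {
      names_b[2:4] <- frd_names
    }
    nodes[[branch]] <- data.frame(
      id = ids, category = branch, name = names_b, synonyms = syn,
      stringsAsFactors = FALSE
    )
    if (n > 1) {
      parent1 <- vapply(2:n, function(i) {
        if (i == 2) 1L else sample.int(i - 1L, 1L)
      }, integer(1))
      e <- data.frame(subject = ids[2:n], predicate = "subclass_of",
                      object = ids[parent1], stringsAsFactors = FALSE)
      extra <- which(stats::runif(n - 1) < 0.2 & (2:n) > 2)
      if (length(extra) > 0) {
        p2 <- vapply(extra, function(k) {
          i <- k + 1L
          cand <- setdiff(seq_len(i - 1L), parent1[k])
          cand[sample.int(length(cand), 1L)]
        }, integer(1))
        e <- rbind(e, data.frame(subject = ids[extra + 1L],
                                 predicate = "subclass_of",
                                 object = ids[p2], stringsAsFactors = FALSE))
      }
      edges[[branch]] <- e
    }
  }
  onto <- ontology(do.call(rbind, nodes),
                   if (length(edges)) do.call(rbind, edges) else
                     data.frame(subject = character(), predicate = character(),
                                object = character()))
  attr(onto, "frd_curies") <- if (nt[["disease"]] >= 4) {
    stats::setNames(vapply(2:4, function(i) curie_for("disease", i), character(1)),
                    frd_names)
  } else character(0)
  onto
}
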