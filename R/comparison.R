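#' Exact-match comparison of the two analysis arms
#'
#' For one disorder, intersects the knowledge-graph-predicted destination
#' CURIEs with the regression features significant after Bonferroni
#' adjustment (`p_adjusted < alpha`). Matching is strict CURIE identity;
#' with `ancestor_aware = TRUE` a prediction also matches any regression
#' feature that is an ontology ancestor of it (off by default).
#'
#' @param predictions [predict_frd_links()] output.
#' @param results A `regression_result` for the same disorder.
#' @param disorder Disorder CURIE.
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @param ontology Required only for `ancestor_aware = TRUE`.
#' @param ancestor_aware Enable ancestor-aware near-matching.
#' @return List of class `comparison_result`: `disorder`, `kg_only`,
#'   `regression_only`, `exact_matches` (data.frame with the prediction
#'   score and the regression row attached).
#' @export
exact_match <- function(predictions, results, disorder, alpha = 0.05,
                        ontology = NULL, ancestor_aware = FALSE) {
  preds <- predictions[predictions$source == disorder, , drop = FALSE]
  kg_set <- unique(preds$destination)
  sig <- results[!is.na(results$p_adjusted) & results$p_adjusted < alpha, ,
                 drop = FALSE]
  reg_set <- unique(sig$feature)
  matched <- intersect(kg_set, reg_set)
  if (ancestor_aware && !is.null(ontology) && length(kg_set) > 0) {
    anc <- ancestors_of(ontology, kg_set)
    extra <- reg_set[reg_set %in% anc]
    matched <- union(matched, extra)
  }
  md <- sig[sig$feature %in% matched, , drop = FALSE]
  md$score <- preds$score[match(md$feature, preds$destination)]
  rownames(md) <- NULL
  structure(list(
    disorder = disorder,
    kg_only = setdiff(kg_set, matched),
    regression_only = setdiff(reg_set, matched),
    exact_matches = md
  ), class = "comparison_result")
}

# All ancestors (transitive subclass_of closure) of a set of CURIEs.
ancestors_of <- function(ontology, curies) {
  parent_map <- split(ontology$edges$object, ontology$edges$subject)
  seen <- character(0)
  frontier <- curies
  while (length(frontier) > 0) {
    nxt <- unique(unlist(parent_map[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %d KG-only, %d regression-only, %d exact matches\n",
              x$disorder, length(x$kg_only), length(x$regression_only),
              nrow(x$exact_matches)))
  invisible(x)
}

#' Render the combined two-arm report
#'
#' Writes one TSV per disorder (regression rows with a `matched` flag and
#' the KG prediction score where matched) and a markdown summary with
#' per-disorder and total counts plus run metadata.
#'
#' @param comparisons List of `comparison_result` objects.
#' @param regression_results Named list of `regression_result` data.frames
#'   (by disorder CURIE).
#' @param metrics Named list of run metadata (seeds, AUROC, params...).
#' @param out_dir Output directory.
#' @param alpha Significance threshold used (recorded in the report).
#' @return Invisibly, the summary file path.
#' @export
render_report <- function(comparisons, regression_results = list(),
                          metrics = list(), out_dir, alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  lines <- c("# Two-arm comparison report", "")
  if (length(metrics) > 0) {
    lines <- c(lines, "## Run metadata", "",
               vapply(names(metrics), function(k) {
                 sprintf("- %s: %s", k, paste(format(metrics[[k]]), collapse = ", "))
               }, character(1)), "")
  }
  lines <- c(lines, "## Per-disorder counts", "")
  total <- 0L
  for (cmp in comparisons) {
    n_kg <- length(cmp$kg_only) + nrow(cmp$exact_matches)
    n_reg <- length(cmp$regression_only) + nrow(cmp$exact_matches)
    n_match <- nrow(cmp$exact_matches)
    total <- total + n_match
    lines <- c(lines, sprintf(
      "- %s: %d predictions, %d significant features (adjusted p < %s), %d exact matches",
      cmp$disorder, n_kg, n_reg, format(alpha), n_match))
    if (n_match > 0) {
      lines <- c(lines, vapply(seq_len(n_match), function(i) {
        r <- cmp$exact_matches[i, ]
        sprintf("    - **%s** (%s): score %.3f, OR %.2f [%.2f, %.2f], adjusted p %.3g",
                r$feature, r$label, r$score, r$odds_ratio, r$ci_low,
                r$ci_high, r$p_adjusted)
      }, character(1)))
    }
    res <- regression_results[[cmp$disorder]]
    if (!is.null(res) && nrow(res) > 0) {
      res$matched <- res$feature %in% cmp$exact_matches$feature
      res$kg_score <- cmp$exact_matches$score[match(res$feature,
                                                    cmp$exact_matches$feature)]
      f <- file.path(out_dir, paste0(gsub(":", "_", cmp$disorder), ".tsv"))
      utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  lines <- c(lines, "", sprintf("Total exact matches: %d", total))
  path <- file.path(out_dir, "summary.md")
  writeLines(lines, path)
  invisible(path)
}
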