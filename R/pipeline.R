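#' Run the knowledge-graph arm on a synthetic bundle
#'
#' Maps responses to assertions, builds and reduces the graph to its largest
#' component, performs the connectivity-preserving 70/30 edge split, embeds
#' the training graph and evaluates the edge classifier's test AUROC, then
#' embeds the full graph, retrains on all edges, and predicts
#' disorder-variable links above the score threshold.
#'
#' @param bundle A `synthetic_bundle`.
#' @param emb_params An [embedding_params()].
#' @param clf_params A [classifier_params()].
#' @param test_fraction Held-out edge fraction (default 0.3).
#' @param frd_nodes Disorder source CURIEs (default: the bundle's FRDs).
#' @return List with `graph` (largest component), `components`
#'   (pre-extraction summary), `split`, `auroc`, `predictions`, `unmapped`,
#'   and the embeddings used.
#' @export
run_kg_arm <- function(bundle, emb_params = embedding_params(),
                       clf_params = classifier_params(),
                       test_fraction = 0.3, frd_nodes = NULL) {
  key <- validate_translation_key(bundle$translation_key, bundle$ontology)
  mapped <- map_responses(bundle$responses, key, bundle$ontology)
  question_curies <- unique(bundle$questions$curie)
  full <- build_graph(mapped$assertions, bundle$ontology,
                      supplemental = bundle$supplemental_links,
                      question_curies = question_curies)
  comps <- connected_components(full)
  graph <- extract_largest_component(full)

  split <- split_edges(graph, fraction = test_fraction,
                       seed = clf_params$seed)
  train_graph <- knowledge_graph(graph$nodes, split$train_edges)
  emb_train <- embed_graph(train_graph, emb_params)
  clf <- train_edge_classifier(split, emb_train, clf_params)
  auc <- evaluate_auroc(clf, split, emb_train, seed = clf_params$seed + 1L)

  emb_full <- embed_graph(graph, emb_params)
  if (is.null(frd_nodes)) {
    frd_nodes <- unname(attr(bundle$ontology, "frd_curies"))
  }
  preds <- predict_frd_links(graph, emb_full, clf_params, frd_nodes)

  list(graph = graph, full_graph = full, components = comps, split = split,
       auroc = auc, predictions = preds, unmapped = mapped$unmapped,
       emb_train = emb_train, emb_full = emb_full)
}

#' Run both analysis arms and compare them
#'
#' End-to-end driver: knowledge-graph arm, regression arm, and per-disorder
#' exact-match comparison. When `out_dir` is given, all artifacts are
#' written (KGX TSVs, embedding, predictions, regression TSVs, comparison
#' report).
#'
#' @param bundle A `synthetic_bundle`.
#' @param seed Integer seed driving both arms.
#' @param alpha Adjusted-significance threshold for the comparison.
#' @param emb_params,clf_params Arm-one settings; seeds default to `seed`.
#' @param out_dir Optional output directory.
#' @return List with `kg`, `regression`, `comparisons`, and the artifact
#'   paths when written.
#' @export
run_full_analysis <- function(bundle, seed = 1L, alpha = 0.05,
                              emb_params = NULL, clf_params = NULL,
                              out_dir = NULL) {
  if (is.null(emb_params)) emb_params <- embedding_params(seed = seed)
  if (is.null(clf_params)) clf_params <- classifier_params(seed = seed)
  kg <- run_kg_arm(bundle, emb_params, clf_params)
  reg <- run_regression_arm(bundle, seed = seed)
  frds <- intersect(unique(kg$predictions$source), names(reg$results))
  frds <- union(frds, names(reg$results))
  comparisons <- lapply(frds, function(d) {
    res <- reg$results[[d]]
    if (is.null(res)) {
      res <- structure(data.frame(feature = character(),
                                  p_adjusted = numeric()),
                       class = c("regression_result", "data.frame"))
    }
    exact_match(kg$predictions, res, d, alpha = alpha)
  })
  names(comparisons) <- frds

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_kgx(kg$graph, file.path(out_dir, "kg_nodes.tsv"),
              file.path(out_dir, "kg_edges.tsv"))
    write_embedding(kg$emb_full, emb_params,
                    file.path(out_dir, "embedding.tsv"))
    utils::write.table(kg$predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (d in names(reg$results)) {
      if (is.null(reg$results[[d]])) next
      utils::write.table(reg$results[[d]],
                         file.path(out_dir, paste0("regression_",
                                                   gsub(":", "_", d), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    metrics <- list(seed = seed, auroc = kg$auroc,
                    achieved_test_fraction = kg$split$achieved_test_fraction,
                    n_components = kg$components$n_components,
                    score_threshold = clf_params$score_threshold)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE)
    render_report(comparisons, reg$results, metrics,
                  file.path(out_dir, "report"), alpha = alpha)
    paths <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  }
  list(kg = kg, regression = reg, comparisons = comparisons, paths = paths)
}
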