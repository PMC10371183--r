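#' Edge-classifier hyperparameters
#'
#' Defaults follow the analysis design: a random forest of 501 trees with
#' maximum depth 15, 1:1 negative sampling, and predicted links retained at
#' score > 0.8.
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed (forest construction and negative sampling).
#' @param negatives_per_positive Negatives sampled per positive edge.
#' @param score_threshold Retention threshold for predicted links, in (0,1).
#' @param operator Edge-embedding operator (see [embed_edge()]).
#' @param max_train_edges Cap on the number of positive edges used to fit
#'   the forest. Graphs beyond desk scale carry tens of thousands of mostly
#'   redundant person-term edges; a seeded uniform subsample of this size
#'   keeps forest construction fast without a measurable AUROC cost. Use
#'   `Inf` to train on every edge.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(n_trees = 501, max_depth = 15, seed = 1L,
                              negatives_per_positive = 1,
                              score_threshold = 0.8, operator = "hadamard",
                              max_train_edges = 4000) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must be in [0, 1]")
  }
  if (max_train_edges < 1) stop("max_train_edges must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed),
                 negatives_per_positive = negatives_per_positive,
                 score_threshold = score_threshold,
                 operator = operator,
                 max_train_edges = max_train_edges),
            class = "classifier_params")
}

edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v))

#' Connectivity-preserving train/test edge split
#'
#' Edges are shuffled with a seeded RNG and streamed through a union-find:
#' edges joining two components become the spanning forest (always kept in
#' the training portion); the remaining edges are removable without
#' disconnecting anything, and the first of them (in shuffle order) up to
#' the target fraction form the test portion. Removing the whole test set
#' therefore leaves the component count unchanged. On sparse graphs the
#' achieved fraction can fall below the target (down to 0 on trees, with a
#' warning).
#'
#' @param graph A [knowledge_graph()] (typically the largest component).
#' @param fraction Target test fraction (default 0.3 for a 70/30 split).
#' @param seed Integer seed.
#' @return List of class `edge_split`: `train_edges`, `test_edges` (both
#'   data.frames `subject, predicate, object`), `target_test_fraction`,
#'   `achieved_test_fraction`.
#' @export
split_edges <- function(graph, fraction = 0.3, seed = 1L) {
  m <- nrow(graph$edges)
  if (m == 0) stop("graph has no edges")
  set.seed(seed)
  ord <- sample.int(m)
  idx <- stats::setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
  u <- idx[graph$edges$subject[ord]]
  v <- idx[graph$edges$object[ord]]
  parent <- seq_len(nrow(graph$nodes))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  removable <- logical(m)
  for (i in seq_len(m)) {
    ru <- find(u[i])
    rv <- find(v[i])
    if (ru == rv) removable[i] <- TRUE else parent[ru] <- rv
  }
  n_target <- floor(fraction * m)
  take <- which(removable)
  if (length(take) > n_target) take <- take[seq_len(n_target)]
  if (length(take) == 0) {
    warning("no removable edges (all edges are bridges); test set is empty")
  }
  test_idx <- sort(ord[take])
  train <- graph$edges[setdiff(seq_len(m), test_idx), , drop = FALSE]
  test <- graph$edges[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train_edges = train, test_edges = test,
                 target_test_fraction = fraction,
                 achieved_test_fraction = nrow(test) / m),
            class = "edge_split")
}

#' Sample non-edges uniformly
#'
#' Draws `n` unordered node pairs uniformly, rejecting self-pairs,
#' duplicates, existing edges, and any pair listed in `exclude`.
#'
#' @param graph A [knowledge_graph()] (>= 2 nodes).
#' @param n Number of negative pairs.
#' @param seed Integer seed.
#' @param exclude Optional extra edge data.frame (`subject`, `object`) to
#'   avoid.
#' @return data.frame `subject, object` of `n` non-edges.
#' @export
sample_negative_edges <- function(graph, n, seed = 1L, exclude = NULL) {
  ids <- graph$nodes$id
  N <- length(ids)
  if (N < 2) stop("graph must have >= 2 nodes")
  existing <- unique(edge_key(graph$edges$subject, graph$edges$object))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    existing <- unique(c(existing, edge_key(exclude$subject, exclude$object)))
  }
  n_possible <- N * (N - 1) / 2 - length(existing)
  if (n > n_possible) {
    stop("requested ", n, " negative edges but only ", n_possible,
         " non-edges exist")
  }
  set.seed(seed)
  got <- character(0)
  out_u <- character(0); out_v <- character(0)
  while (length(out_u) < n) {
    k <- max(2 * (n - length(out_u)), 100)
    a <- ids[sample.int(N, k, replace = TRUE)]
    b <- ids[sample.int(N, k, replace = TRUE)]
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    key <- edge_key(a, b)
    keep <- !(key %in% existing) & !(key %in% got) & !duplicated(key)
    a <- a[keep]; b <- b[keep]; key <- key[keep]
    out_u <- c(out_u, a); out_v <- c(out_v, b); got <- c(got, key)
  }
  data.frame(subject = out_u[seq_len(n)], object = out_v[seq_len(n)],
             stringsAsFactors = FALSE)
}

# Fit a probability forest on edge features for positive vs negative pairs.
fit_edge_forest <- function(pos_pairs, neg_pairs, emb, params) {
  X <- rbind(edge_features(pos_pairs, emb, params$operator),
             edge_features(neg_pairs, emb, params$operator))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(X)
  df$y <- factor(rep(c("edge", "nonedge"), c(nrow(pos_pairs), nrow(neg_pairs))),
                 levels = c("edge", "nonedge"))
  ranger::ranger(y ~ ., data = df, num.trees = params$n_trees,
                 max.depth = params$max_depth, probability = TRUE,
                 seed = params$seed, num.threads = 1)
}

score_pairs <- function(model, pairs, emb, operator) {
  X <- edge_features(pairs, emb, operator)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  stats::predict(model, data = data.frame(X), num.threads = 1)$predictions[, "edge"]
}

#' Train the random-forest edge classifier
#'
#' Fits a probability forest on the edge-embedded training positives and an
#' equal-by-default number of uniformly sampled negatives (non-edges of the
#' full graph, so no held-out test edge leaks in as a negative).
#'
#' @param split An [split_edges()] result.
#' @param emb Embedding matrix covering all endpoint nodes.
#' @param params A [classifier_params()].
#' @return List of class `edge_classifier` with the fitted model, operator,
#'   and the negatives used.
#' @export
train_edge_classifier <- function(split, emb, params = classifier_params()) {
  if (nrow(split$train_edges) == 0) stop("empty training edge set")
  pos <- as.matrix(split$train_edges[, c("subject", "object")])
  if (is.finite(params$max_train_edges) &&
      nrow(pos) > params$max_train_edges) {
    set.seed(params$seed)
    pos <- pos[sample.int(nrow(pos), params$max_train_edges), , drop = FALSE]
  }
  all_edges <- rbind(split$train_edges[, c("subject", "object")],
                     split$test_edges[, c("subject", "object")])
  pseudo_graph <- list(nodes = data.frame(id = rownames(emb)),
                       edges = all_edges)
  n_neg <- round(params$negatives_per_positive * nrow(pos))
  neg <- sample_negative_edges(pseudo_graph, n_neg, seed = params$seed)
  model <- fit_edge_forest(pos, as.matrix(neg), emb, params)
  structure(list(model = model, params = params, negatives = neg),
            class = "edge_classifier")
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: the probability a random positive outscores a
#' random negative, ties counting one half.
#'
#' @param pos_scores,neg_scores Numeric score vectors (both nonempty).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stop("need scores from both classes")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate the edge classifier on the held-out test edges
#'
#' Scores the test positives against freshly sampled test negatives (equal
#' count, excluding every edge of the graph and the training negatives) and
#' returns the rank-statistic AUROC.
#'
#' @param classifier An [train_edge_classifier()] result.
#' @param split The [split_edges()] result.
#' @param emb Embedding matrix.
#' @param seed Integer seed for the test negatives.
#' @return AUROC (numeric scalar).
#' @export
evaluate_auroc <- function(classifier, split, emb, seed = 1L) {
  if (nrow(split$test_edges) == 0) stop("empty test edge set")
  pos <- as.matrix(split$test_edges[, c("subject", "object")])
  all_edges <- rbind(split$train_edges[, c("subject", "object")],
                     split$test_edges[, c("subject", "object")])
  pseudo_graph <- list(nodes = data.frame(id = rownames(emb)),
                       edges = all_edges)
  neg <- sample_negative_edges(pseudo_graph, nrow(pos), seed = seed,
                               exclude = classifier$negatives)
  op <- classifier$params$operator
  auroc(score_pairs(classifier$model, pos, emb, op),
        score_pairs(classifier$model, as.matrix(neg), emb, op))
}

#' Predict disorder-variable links from the full graph
#'
#' Retrains the forest on the full (no-holdout) edge set using the full-data
#' embedding, then scores each disorder node as "source" against every
#' candidate destination (all non-person nodes except the disorder itself).
#' Predictions above the score threshold are returned sorted by decreasing
#' score, ties broken by destination id.
#'
#' @param graph The largest-component [knowledge_graph()].
#' @param emb Full-graph embedding matrix.
#' @param params A [classifier_params()].
#' @param frd_nodes Character vector of disorder CURIEs to use as sources.
#' @param model Optional pre-trained `edge_classifier` fit on the full edge
#'   set; trained here when `NULL`.
#' @return data.frame `source, source_label, destination, destination_label,
#'   score` with attribute `model` (the full-data classifier).
#' @export
predict_frd_links <- function(graph, emb, params = classifier_params(),
                              frd_nodes, model = NULL) {
  present <- frd_nodes %in% graph$nodes$id
  if (any(!present)) {
    warning("FRD nodes absent from the graph, skipped: ",
            paste(frd_nodes[!present], collapse = ", "))
    frd_nodes <- frd_nodes[present]
  }
  if (is.null(model)) {
    full_split <- structure(list(train_edges = graph$edges,
                                 test_edges = graph$edges[0, , drop = FALSE],
                                 target_test_fraction = 0,
                                 achieved_test_fraction = 0),
                            class = "edge_split")
    model <- train_edge_classifier(full_split, emb, params)
  }
  labels <- stats::setNames(graph$nodes$name, graph$nodes$id)
  candidates_all <- graph$nodes$id[graph$nodes$category != "person"]
  out <- lapply(frd_nodes, function(src) {
    dest <- setdiff(candidates_all, src)
    if (length(dest) == 0) return(NULL)
    pairs <- cbind(rep(src, length(dest)), dest)
    s <- score_pairs(model$model, pairs, emb, params$operator)
    # threshold 0 keeps every candidate (scores are bounded below by 0)
    keep <- if (params$score_threshold <= 0) rep(TRUE, length(s)) else
      s > params$score_threshold
    data.frame(source = rep(src, sum(keep)),
               source_label = rep(unname(labels[src]), sum(keep)),
               destination = dest[keep],
               destination_label = unname(labels[dest[keep]]),
               score = s[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(source = character(), source_label = character(),
                      destination = character(),
                      destination_label = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$source, -res$score, res$destination), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "model") <- model
  res
}
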