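#' Embedding hyperparameters
#'
#' Defaults are sized for desk-scale synthetic graphs: dimension 32, 10
#' uniform random walks of length 40 per node, window 5, 5 negatives per
#' positive, 5 epochs, initial learning rate 0.025 with linear decay.
#' Training is single-threaded by contract so a fixed seed yields an
#' identical matrix.
#'
#' @param dimension Embedding dimension (>= 2).
#' @param walks_per_node,walk_length Random-walk corpus size.
#' @param window Skip-gram context window.
#' @param negatives_per_positive Negative samples per positive pair.
#' @param epochs Training epochs; 0 returns the seeded initialization.
#' @param learning_rate Initial SGD learning rate.
#' @param seed Integer seed.
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(dimension = 32, walks_per_node = 10,
                             walk_length = 40, window = 5,
                             negatives_per_positive = 5, epochs = 5,
                             learning_rate = 0.025, seed = 1L) {
  if (dimension < 2) stop("configuration error: dimension must be >= 2")
  if (walk_length < 2) stop("walk_length must be >= 2")
  if (window < 1) stop("window must be >= 1")
  structure(list(dimension = as.integer(dimension),
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "embedding_params")
}

# CSR adjacency of the undirected view; node order follows graph$nodes$id.
graph_csr <- function(graph) {
  ids <- graph$nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  u <- idx[graph$edges$subject]
  v <- idx[graph$edges$object]
  from <- c(u, v); to <- c(v, u)
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  deg <- tabulate(from, nbins = length(ids))
  list(ids = ids,
       offsets = as.integer(c(0, cumsum(deg))),
       neighbors = as.integer(to - 1L))
}

#' Generate a uniform random-walk corpus
#'
#' `walks_per_node` walks of exactly `walk_length` nodes start from every
#' node; each next node is drawn uniformly from the current node's
#' neighbors (first-order DeepWalk walks). Requires a connected graph.
#'
#' @param graph A [knowledge_graph()] (its largest component).
#' @param params An [embedding_params()].
#' @return Integer matrix of 1-based node indices, one walk per row, with
#'   attribute `node_ids` giving the index-to-id mapping.
#' @export
generate_walks <- function(graph, params) {
  csr <- graph_csr(graph)
  if (nrow(graph$nodes) >= 2 && any(diff(csr$offsets) == 0)) {
    stop("internal error: graph passed to generate_walks has isolated nodes")
  }
  walks <- cpp_generate_walks(csr$offsets, csr$neighbors,
                              params$walks_per_node, params$walk_length,
                              as.double(params$seed)) + 1L
  attr(walks, "node_ids") <- csr$ids
  walks
}

#' Train skip-gram node embeddings with negative sampling
#'
#' For each center node and every context node within the window, one
#' positive update and `negatives_per_positive` negative updates (targets
#' drawn from the corpus unigram distribution raised to the 0.75 power) are
#' applied under the logistic loss, with linear learning-rate decay. The
#' center-vector matrix is returned.
#'
#' @param corpus Walk matrix from [generate_walks()].
#' @param params An [embedding_params()].
#' @param report_loss If `TRUE`, attach the per-epoch mean logistic loss as
#'   attribute `epoch_loss`.
#' @return Numeric matrix, one row per node (rownames = node ids),
#'   `dimension` columns.
#' @export
train_skipgram <- function(corpus, params, report_loss = FALSE) {
  if (nrow(corpus) == 0) stop("empty walk corpus")
  ids <- attr(corpus, "node_ids")
  emb <- cpp_train_sgns(corpus - 1L, length(ids), params$dimension,
                        params$window, params$negatives_per_positive,
                        params$epochs, params$learning_rate,
                        as.double(params$seed), report_loss)
  loss <- attr(emb, "epoch_loss")
  out <- t(emb)
  rownames(out) <- ids
  if (report_loss) attr(out, "epoch_loss") <- loss
  out
}

#' Embed a knowledge graph's nodes
#'
#' Convenience wrapper: [generate_walks()] then [train_skipgram()].
#'
#' @inheritParams generate_walks
#' @param report_loss Passed to [train_skipgram()].
#' @return Embedding matrix with node-id rownames.
#' @export
embed_graph <- function(graph, params = embedding_params(),
                        report_loss = FALSE) {
  train_skipgram(generate_walks(graph, params), params, report_loss)
}

#' Combine two node vectors into an edge feature vector
#'
#' All four operators are symmetric in their arguments: hadamard
#' (element-wise product, the default), average, L1 (absolute difference)
#' and L2 (squared difference).
#'
#' @param u,v Node ids.
#' @param emb Embedding matrix with node-id rownames.
#' @param operator One of `"hadamard"`, `"average"`, `"L1"`, `"L2"`.
#' @return Numeric vector of length `ncol(emb)`.
#' @export
embed_edge <- function(u, v, emb,
                       operator = c("hadamard", "average", "L1", "L2")) {
  operator <- match.arg(operator)
  if (!(u %in% rownames(emb)) || !(v %in% rownames(emb))) {
    stop("unknown node id: ", paste(setdiff(c(u, v), rownames(emb)),
                                    collapse = ", "))
  }
  edge_features(matrix(c(u, v), 1), emb, operator)[1, ]
}

# Vectorized edge-feature construction for an n x 2 matrix of node ids.
edge_features <- function(pairs, emb, operator = "hadamard") {
  x <- emb[pairs[, 1], , drop = FALSE]
  y <- emb[pairs[, 2], , drop = FALSE]
  switch(operator,
         hadamard = x * y,
         average = (x + y) / 2,
         L1 = abs(x - y),
         L2 = (x - y)^2,
         stop("unknown edge operator: ", operator))
}

#' Write an embedding matrix as TSV with a JSON parameter sidecar
#'
#' @param emb Embedding matrix.
#' @param params The [embedding_params()] used.
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return Invisibly, the paths written.
#' @export
write_embedding <- function(emb, params, path) {
  df <- data.frame(node_id = rownames(emb), emb, stringsAsFactors = FALSE)
  names(df) <- c("node_id", paste0("d", seq_len(ncol(emb))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(unclass(params), sidecar, auto_unbox = TRUE)
  invisible(c(path, sidecar))
}
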