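#' Heterogeneous knowledge graph
#'
#' Nodes are persons and ontology terms; edges are typed triples
#' `(subject, predicate, object)`. Edges are stored directed, but all
#' connectivity computations and random walks treat the graph as undirected.
#'
#' @param nodes data.frame `id, category, name`.
#' @param edges data.frame `subject, predicate, object`.
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "category", "name") %in% names(nodes)),
            all(c("subject", "predicate", "object") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  missing_ep <- setdiff(c(edges$subject, edges$object), nodes$id)
  if (length(missing_ep) > 0) {
    stop("edges reference unknown nodes: ", paste(missing_ep, collapse = ", "))
  }
  if (any(edges$subject == edges$object)) stop("self-loops are not allowed")
  cat_of <- stats::setNames(nodes$category, nodes$id)
  if (any(cat_of[edges$subject] == "person" & cat_of[edges$object] == "person")) {
    stop("person-person edges are not allowed")
  }
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes, %d edges (%d person nodes)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$nodes$category == "person")))
  invisible(x)
}

#' Build the knowledge graph from assertions, ontology and supplemental links
#'
#' One person node per respondent, one node per ontology term (the full
#' ontology content is merged, including terms untouched by any answer, which
#' is what produces the many singleton components), assertion edges
#' person -> term, `subclass_of` edges for the ontology hierarchy, and
#' supplemental food -> chemical (`applied_with`) / food -> nutrient
#' (`contains_nutrient`) edges. Supplemental rows whose food term is not
#' covered by any survey question are dropped when `question_curies` is
#' given. Duplicate identical edges collapse to one; the build is
#' order-independent.
#'
#' @param assertions Assertion data.frame from [map_responses()].
#' @param ontology An [ontology()].
#' @param supplemental Optional data.frame `subject, predicate, object`.
#' @param question_curies Optional character vector of CURIEs covered by the
#'   translation key, used to filter supplemental links.
#' @return A [knowledge_graph()].
#' @export
build_graph <- function(assertions, ontology, supplemental = NULL,
                        question_curies = NULL) {
  bad <- !ontology_contains(ontology, assertions$object_curie)
  if (any(bad)) {
    stop("assertions reference CURIEs absent from the ontology: ",
         paste(unique(assertions$object_curie[bad]), collapse = ", "))
  }
  persons <- sort(unique(assertions$respondent_id))
  nodes <- rbind(
    data.frame(id = persons, category = "person", name = persons,
               stringsAsFactors = FALSE),
    ontology$nodes[, c("id", "category", "name")]
  )
  edges <- data.frame(subject = assertions$respondent_id,
                      predicate = assertions$predicate,
                      object = assertions$object_curie,
                      stringsAsFactors = FALSE)
  edges <- rbind(edges, ontology$edges[, c("subject", "predicate", "object")])
  if (!is.null(supplemental) && nrow(supplemental) > 0) {
    supp <- supplemental
    if (!is.null(question_curies)) {
      supp <- supp[supp$subject %in% question_curies, , drop = FALSE]
    }
    missing_obj <- !ontology_contains(ontology, c(supp$subject, supp$object))
    if (any(missing_obj)) {
      stop("supplemental links reference CURIEs absent from the ontology")
    }
    edges <- rbind(edges, supp[, c("subject", "predicate", "object")])
  }
  edges <- unique(edges)
  edges <- edges[order(edges$subject, edges$predicate, edges$object), ]
  rownames(edges) <- NULL
  knowledge_graph(nodes, edges)
}

# igraph view (undirected) including isolated nodes.
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("subject", "object")],
    directed = FALSE,
    vertices = graph$nodes$id
  )
}

# Identify the largest component's member ids; ties broken by the smallest
# lexicographic member node id.
largest_component_members <- function(graph) {
  comp <- igraph::components(as_igraph(graph))
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    min_member <- vapply(biggest, function(k) {
      min(graph$nodes$id[comp$membership == k])
    }, character(1))
    biggest <- biggest[order(min_member)][1]
  }
  list(members = graph$nodes$id[comp$membership == biggest], comp = comp)
}

#' Connected-component summary of a knowledge graph
#'
#' Components are computed on the undirected view. `removed_persons` counts
#' person nodes falling outside the largest component (the respondents whose
#' data would be eliminated by largest-component extraction).
#'
#' @param graph A [knowledge_graph()].
#' @return List of class `component_summary`: `n_components`,
#'   `component_sizes` (decreasing), `largest_size`, `removed_persons`,
#'   `removed_fraction`.
#' @export
connected_components <- function(graph) {
  if (nrow(graph$nodes) == 0) stop("empty graph")
  lc <- largest_component_members(graph)
  person_ids <- graph$nodes$id[graph$nodes$category == "person"]
  outside <- setdiff(person_ids, lc$members)
  structure(list(
    n_components = lc$comp$no,
    component_sizes = sort(lc$comp$csize, decreasing = TRUE),
    largest_size = max(lc$comp$csize),
    removed_persons = length(outside),
    removed_fraction = if (length(person_ids) > 0) {
      length(outside) / length(person_ids)
    } else 0
  ), class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf(paste0("<component_summary> %d components, largest %d nodes, ",
                     "%d persons outside (%.1f%%)\n"),
              x$n_components, x$largest_size, x$removed_persons,
              100 * x$removed_fraction))
  invisible(x)
}

#' Extract the largest connected component
#'
#' @param graph A [knowledge_graph()].
#' @return A [knowledge_graph()] restricted to the largest component (ties
#'   broken by smallest lexicographic member id). Idempotent on connected
#'   graphs.
#' @export
extract_largest_component <- function(graph) {
  members <- largest_component_members(graph)$members
  nodes <- graph$nodes[graph$nodes$id %in% members, , drop = FALSE]
  edges <- graph$edges[graph$edges$subject %in% members &
                         graph$edges$object %in% members, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  knowledge_graph(nodes, edges)
}

#' Write / read a knowledge graph as KGX-dialect TSVs
#'
#' Node file columns: `id, category, name`; edge file columns:
#' `subject, predicate, object`. The round trip is the identity up to edge
#' ordering.
#'
#' @param graph A [knowledge_graph()].
#' @param node_path,edge_path TSV file paths.
#' @return `write_kgx` invisibly returns the paths; `read_kgx` returns the
#'   graph.
#' @export
write_kgx <- function(graph, node_path, edge_path) {
  utils::write.table(graph$nodes[, c("id", "category", "name")], node_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph$edges[, c("subject", "predicate", "object")],
                     edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}

read_kgx_table <- function(path, cols) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty KGX file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (!identical(header, cols)) {
    stop("malformed KGX header in ", path, " (line 1): expected ",
         paste(cols, collapse = ","))
  }
  nfield <- lengths(parts[-1])
  bad <- which(nfield != length(cols))
  if (length(bad) > 0) {
    stop("malformed KGX row in ", path, " at line ", bad[1] + 1)
  }
  if (length(parts) == 1) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  m <- do.call(rbind, parts[-1])
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' @rdname write_kgx
#' @export
read_kgx <- function(node_path, edge_path) {
  nodes <- read_kgx_table(node_path, c("id", "category", "name"))
  edges <- read_kgx_table(edge_path, c("subject", "predicate", "object"))
  knowledge_graph(nodes, edges)
}
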