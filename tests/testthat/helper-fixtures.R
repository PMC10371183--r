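# Shared fixtures, built in code.

# Tiny hand-made ontology: a 3-term chemical chain with a branded synonym,
# plus small disease/phenotype/food branches.
tiny_ontology <- function() {
  nodes <- data.frame(
    id = c("CHEBI:0000001", "CHEBI:0006375", "CHEBI:0000002",
           "MONDO:0000001", "MONDO:0000002",
           "HP:0000001", "HP:0000138",
           "FOODON:0000001", "FOODON:0000002"),
    category = c("chemical", "chemical", "chemical",
                 "disease", "disease", "phenotype", "phenotype",
                 "food", "food"),
    name = c("chemical root", "lansoprazole", "benzimidazole",
             "disease root", "endometriosis",
             "phenotype root", "ovarian cyst",
             "food root", "carrot"),
    synonyms = c("", "Prevacid", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    subject = c("CHEBI:0006375", "CHEBI:0000002", "MONDO:0000002",
                "HP:0000138", "FOODON:0000002"),
    predicate = "subclass_of",
    object = c("CHEBI:0000002", "CHEBI:0000001", "MONDO:0000001",
               "HP:0000001", "FOODON:0000001"),
    stringsAsFactors = FALSE
  )
  frdlink::ontology(nodes, edges)
}

tiny_key <- function(onto = tiny_ontology()) {
  key <- data.frame(
    question_id = c("q_med", "q_dis", "q_carrot", "q_cat"),
    response_type = c("free_text", "binary", "ordinal_frequency", "categorical"),
    predicate = c("affected_by", "has_disease", "consumes", "has_phenotype"),
    curie_or_map = c("MATCH", "MONDO:0000002", "FOODON:0000002",
                     "cyst=HP:0000138;none=HP:0000001"),
    stringsAsFactors = FALSE
  )
  frdlink::validate_translation_key(key, onto)
}

# A small graph from explicit edges; node categories default to "other".
graph_from_edges <- function(edges_df, person_ids = character(0)) {
  ids <- sort(unique(c(edges_df$subject, edges_df$object)))
  nodes <- data.frame(
    id = ids,
    category = ifelse(ids %in% person_ids, "person", "other"),
    name = ids, stringsAsFactors = FALSE
  )
  if (is.null(edges_df$predicate)) edges_df$predicate <- "related_to"
  frdlink::knowledge_graph(nodes, edges_df[, c("subject", "predicate", "object")])
}

# Two k-cliques joined by one bridge edge.
two_clique_graph <- function(k = 10) {
  clique_edges <- function(prefix, k) {
    idx <- t(utils::combn(k, 2))
    data.frame(subject = sprintf("%s%02d", prefix, idx[, 1]),
               predicate = "related_to",
               object = sprintf("%s%02d", prefix, idx[, 2]),
               stringsAsFactors = FALSE)
  }
  e <- rbind(clique_edges("a", k), clique_edges("b", k),
             data.frame(subject = sprintf("a%02d", k), predicate = "related_to",
                        object = "b01", stringsAsFactors = FALSE))
  graph_from_edges(e)
}

# Independent union-find oracle for component counting.
uf_component_count <- function(graph) {
  ids <- graph$nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(graph$edges))) {
    ru <- find(idx[[graph$edges$subject[i]]])
    rv <- find(idx[[graph$edges$object[i]]])
    if (ru != rv) parent[ru] <- rv
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}

# Exhaustive-pair AUROC oracle.
auroc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Small respondent/response fixture for cohort cleaning.
cohort_fixture <- function() {
  respondents <- data.frame(
    respondent_id = sprintf("P%02d", 1:10),
    gender = c(rep("female", 6), rep("male", 4)),
    completed_health = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    completed_internal = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    completed_external = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  questions <- data.frame(
    question_id = c("q_dis", "q_carrot", "q_med"),
    survey = c("health", "internal", "internal"),
    response_type = c("binary", "ordinal_frequency", "free_text"),
    topic = c("t", "t", "t"),
    curie = c("MONDO:0000002", "FOODON:0000002", "CHEBI:0006375"),
    predicate = c("has_disease", "consumes", "affected_by"),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(respondent_id = respondents$respondent_id,
                      question_id = questions$question_id,
                      stringsAsFactors = FALSE)
  grid$survey <- questions$survey[match(grid$question_id, questions$question_id)]
  set.seed(42)
  grid$value <- NA_character_
  bin <- grid$question_id == "q_dis"
  grid$value[bin] <- sample(c("yes", "no"), sum(bin), replace = TRUE)
  ordq <- grid$question_id == "q_carrot"
  grid$value[ordq] <- as.character(sample(0:5, sum(ordq), replace = TRUE))
  ft <- grid$question_id == "q_med"
  grid$value[ft] <- sample(c("lansoprazole", "none"), sum(ft), replace = TRUE)
  list(respondents = respondents, questions = questions, responses = grid)
}
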