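test_that("hand-countable graph: one affirmative answer plus a 3-term chain", {
  nodes <- data.frame(
    id = c("CHEBI:0000001", "CHEBI:0000002", "CHEBI:0006375"),
    category = "chemical",
    name = c("chemical root", "benzimidazole", "lansoprazole"),
    synonyms = "", stringsAsFactors = FALSE)
  edges <- data.frame(subject = c("CHEBI:0006375", "CHEBI:0000002"),
                      predicate = "subclass_of",
                      object = c("CHEBI:0000002", "CHEBI:0000001"),
                      stringsAsFactors = FALSE)
  onto <- ontology(nodes, edges)
  assertions <- data.frame(respondent_id = "P1", predicate = "affected_by",
                           object_curie = "CHEBI:0006375", value = "yes",
                           stringsAsFactors = FALSE)
  g <- build_graph(assertions, onto)
  expect_equal(nrow(g$nodes), 4)  # 1 person + 3 terms
  expect_equal(nrow(g$edges), 3)  # 1 assertion + 2 subclass
  expect_equal(sum(g$edges$predicate == "subclass_of"), 2)
})

test_that("identical answers from two respondents reuse one term node", {
  onto <- tiny_ontology()
  assertions <- data.frame(
    respondent_id = c("P1", "P2"),
    predicate = "affected_by",
    object_curie = "CHEBI:0006375",
    value = c("lansoprazole", "Prevacid"), stringsAsFactors = FALSE)
  g <- build_graph(assertions, onto)
  expect_equal(sum(g$nodes$id == "CHEBI:0006375"), 1)
  inc <- g$edges[g$edges$object == "CHEBI:0006375" &
                   g$edges$predicate == "affected_by", ]
  expect_equal(sort(inc$subject), c("P1", "P2"))
})

test_that("duplicate assertions collapse and builds are order-independent", {
  onto <- tiny_ontology()
  assertions <- data.frame(
    respondent_id = c("P1", "P1", "P2"),
    predicate = "consumes",
    object_curie = "FOODON:0000002",
    value = c("1", "4", "2"), stringsAsFactors = FALSE)
  g1 <- build_graph(assertions, onto)
  g2 <- build_graph(assertions[c(3, 1, 2), ], onto)
  expect_identical(g1$edges, g2$edges)
  expect_equal(sum(g1$edges$subject == "P1" &
                     g1$edges$object == "FOODON:0000002"), 1)
})

test_that("supplemental links attach only to question-mapped foods", {
  onto <- tiny_ontology()
  assertions <- data.frame(respondent_id = "P1", predicate = "consumes",
                           object_curie = "FOODON:0000002", value = "2",
                           stringsAsFactors = FALSE)
  supp <- data.frame(subject = c("FOODON:0000002", "FOODON:0000001"),
                     predicate = "applied_with",
                     object = "CHEBI:0000002", stringsAsFactors = FALSE)
  g <- build_graph(assertions, onto, supplemental = supp,
                   question_curies = "FOODON:0000002")
  expect_true(any(g$edges$subject == "FOODON:0000002" &
                    g$edges$predicate == "applied_with"))
  expect_false(any(g$edges$subject == "FOODON:0000001" &
                     g$edges$predicate == "applied_with"))
})

test_that("edge count equals unique assertions + ontology + applicable links", {
  b <- generate_bundle(synth_config(
    n_respondents = 150,
    n_ontology_terms = c(disease = 10, phenotype = 10, food = 10,
                         chemical = 10, exposure = 10, medical_action = 10),
    n_questions = c(health = 8, internal = 6, external = 4),
    survey_completion_probs = c(health = 1, internal = 1, external = 1),
    seed = 13))
  key <- validate_translation_key(b$translation_key, b$ontology)
  m <- map_responses(b$responses, key, b$ontology)
  qc <- unique(b$questions$curie)
  g <- build_graph(m$assertions, b$ontology, b$supplemental_links, qc)
  ua <- unique(m$assertions[, c("respondent_id", "predicate", "object_curie")])
  supp <- unique(b$supplemental_links[b$supplemental_links$subject %in% qc, ])
  expect_equal(nrow(g$edges),
               nrow(ua) + nrow(b$ontology$edges) + nrow(supp))
})

test_that("component summaries match a union-find oracle", {
  # single edge
  g1 <- graph_from_edges(data.frame(subject = "a", object = "b"))
  s1 <- connected_components(g1)
  expect_equal(s1$n_components, 1)
  expect_equal(s1$largest_size, 2)
  # isolated nodes
  nodes <- data.frame(id = letters[1:5], category = "other", name = letters[1:5])
  gk <- knowledge_graph(nodes, data.frame(subject = character(),
                                          predicate = character(),
                                          object = character()))
  sk <- connected_components(gk)
  expect_equal(sk$n_components, 5)
  expect_true(all(sk$component_sizes == 1))
  # synthetic bundle, cross-checked against the union-find oracle
  b <- generate_bundle(synth_config(
    n_respondents = 100,
    n_ontology_terms = c(disease = 8, phenotype = 8, food = 8, chemical = 8,
                         exposure = 8, medical_action = 8),
    n_questions = c(health = 8, internal = 6, external = 4), seed = 4))
  key <- validate_translation_key(b$translation_key, b$ontology)
  m <- map_responses(b$responses, key, b$ontology)
  g <- build_graph(m$assertions, b$ontology)
  s <- connected_components(g)
  expect_equal(s$n_components, uf_component_count(g))
  expect_equal(sum(s$component_sizes), nrow(g$nodes))
  persons <- g$nodes$id[g$nodes$category == "person"]
  lc <- extract_largest_component(g)
  outside <- setdiff(persons, lc$nodes$id)
  expect_equal(s$removed_fraction, length(outside) / length(persons))
})

test_that("largest-component extraction is idempotent and respects the tie rule", {
  g <- graph_from_edges(data.frame(
    subject = c("a", "b", "x", "y"), object = c("b", "c", "y", "z")))
  # two components of size ~3: tie broken by smallest member id ("a...")
  lc <- extract_largest_component(g)
  expect_true("a" %in% lc$nodes$id)
  expect_false("x" %in% lc$nodes$id)
  expect_identical(extract_largest_component(lc)$edges, lc$edges)
  # clear winner
  g2 <- graph_from_edges(data.frame(
    subject = c("a", "b", "c", "d", "x"), object = c("b", "c", "d", "e", "y")))
  lc2 <- extract_largest_component(g2)
  expect_equal(nrow(lc2$nodes), 5)
  # extraction never removes an edge whose endpoints both survive
  kept <- g2$edges[g2$edges$subject %in% lc2$nodes$id &
                     g2$edges$object %in% lc2$nodes$id, ]
  expect_equal(nrow(lc2$edges), nrow(kept))
})

test_that("KGX round trip is the identity up to edge ordering", {
  dir <- withr::local_tempdir()
  np <- file.path(dir, "n.tsv"); ep <- file.path(dir, "e.tsv")
  # empty graph
  g0 <- knowledge_graph(
    data.frame(id = character(), category = character(), name = character()),
    data.frame(subject = character(), predicate = character(),
               object = character()))
  write_kgx(g0, np, ep)
  r0 <- read_kgx(np, ep)
  expect_equal(nrow(r0$nodes), 0)
  expect_equal(nrow(r0$edges), 0)
  # 4-node example
  onto <- tiny_ontology()
  assertions <- data.frame(respondent_id = "P1", predicate = "affected_by",
                           object_curie = "CHEBI:0006375", value = "x",
                           stringsAsFactors = FALSE)
  g <- build_graph(assertions, onto)
  write_kgx(g, np, ep)
  expect_equal(length(readLines(np)), nrow(g$nodes) + 1)
  expect_equal(length(readLines(ep)), nrow(g$edges) + 1)
  r <- read_kgx(np, ep)
  canon <- function(e) e[order(e$subject, e$predicate, e$object), ]
  expect_equal(canon(r$edges), canon(g$edges), ignore_attr = TRUE)
  expect_equal(r$nodes[order(r$nodes$id), ], g$nodes[order(g$nodes$id), ],
               ignore_attr = TRUE)
})

test_that("malformed KGX rows are rejected with a line number", {
  dir <- withr::local_tempdir()
  np <- file.path(dir, "n.tsv")
  writeLines(c("id\tcategory\tname", "a\tother\tA", "b\tother"), np)
  expect_error(read_kgx_table_err <- read_kgx(np, np), "line 3")
})

test_that("graph invariants are enforced at construction", {
  nodes <- data.frame(id = c("P1", "P2", "T1"),
                      category = c("person", "person", "disease"),
                      name = c("P1", "P2", "T1"))
  expect_error(knowledge_graph(nodes, data.frame(
    subject = "P1", predicate = "x", object = "P1")), "self-loop")
  expect_error(knowledge_graph(nodes, data.frame(
    subject = "P1", predicate = "x", object = "P2")), "person-person")
  expect_error(knowledge_graph(nodes, data.frame(
    subject = "P1", predicate = "x", object = "T9")), "unknown nodes")
  expect_error(connected_components(knowledge_graph(
    nodes[0, ], data.frame(subject = character(), predicate = character(),
                           object = character()))), "empty")
})
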