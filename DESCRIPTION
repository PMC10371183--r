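Package: frdlink
Title: Knowledge-Graph and Regression Analysis of Survey-Derived Links to
    Female Reproductive Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm analysis pipeline for hypothesis generation on
    exposures and comorbidities linked to female reproductive disorders
    (endometriosis, uterine fibroids, ovarian cysts) from ontology-aligned
    survey data. Arm one harmonises survey responses to ontology terms,
    assembles a heterogeneous knowledge graph, embeds its largest component
    with DeepWalk random walks and skip-gram negative sampling, and scores
    candidate disorder-variable links with a random-forest edge classifier
    under a connectivity-preserving edge holdout. Arm two cleans the cohort,
    imputes missing answers with an iterative random-forest scheme, selects
    features by elastic net and permutation importance, and fits logistic
    regressions with Bonferroni-adjusted odds ratios. The two arms are
    compared by exact ontology-term matches. A synthetic-data module
    generates ontologies, survey schemas, and respondent populations with
    planted exposure-disorder effects of known odds ratios.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
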