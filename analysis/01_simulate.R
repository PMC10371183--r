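#!/usr/bin/env Rscript
# Generate the standard synthetic survey bundle and write it to results/.
#
# The bundle is the study's stand-in for restricted cohort data: a six-branch
# ontology, three survey instruments, and a respondent population with three
# planted exposure-disorder effects (odds ratios 3.0, 2.0, 0.4). Later
# scripts regenerate the bundle from the same seed instead of re-reading the
# TSVs, so every stage is deterministic from this one constant.

suppressMessages(library(frdlink))
SEED <- 1L

bundle <- standard_bundle(SEED)
dir.create("results/bundle", recursive = TRUE, showWarnings = FALSE)
write_bundle(bundle, "results/bundle")

cat("respondents:", nrow(bundle$respondents), "\n")
cat("questions:  ", nrow(bundle$questions), "\n")
cat("responses:  ", nrow(bundle$responses), "\n")
cat("ontology:   ", nrow(bundle$ontology$nodes), "terms,",
    nrow(bundle$ontology$edges), "subclass edges\n")
cat("planted effects:\n")
print(bundle$truth, row.names = FALSE)
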