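---
title: "Methods: the two-arm survey-to-knowledge-graph pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-arm survey-to-knowledge-graph pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scientific setting

`frdlink` implements a two-arm analysis for generating hypotheses about
exposures and comorbidities associated with female reproductive disorders
(FRDs: endometriosis, uterine fibroids, ovarian cysts) from ontology-aligned
survey data.

* **Arm one (knowledge graph).** Survey answers are harmonised to ontology
  CURIEs, assembled into a heterogeneous person-term graph, embedded with
  DeepWalk + skip-gram negative sampling, and a random-forest edge classifier
  scores candidate (disorder, term) links.
* **Arm two (epidemiology).** The female, all-surveys-complete cohort forms
  a wide per-CURIE feature table; missing answers are imputed by an
  iterative random-forest scheme; per-disorder features are selected by
  elastic net and permutation importance and fitted jointly by logistic
  regression with Bonferroni-adjusted odds ratios.
* **Comparison.** The arms are reconciled by exact CURIE identity between
  above-threshold graph predictions and Bonferroni-significant regression
  features.

Because cohort data of this kind are access-restricted, the package ships a
synthetic generator whose outputs drive every analysis and test.

# Synthetic generator

`synth_config()` describes a study: a six-branch ontology (MONDO diseases,
HP phenotypes, FOODON foods, CHEBI chemicals, ECTO exposures, MAXO medical
actions; 50 terms per branch by default), three survey instruments (health,
internal, external), and a respondent population. Disorder status follows an
additive-logit model: each planted effect contributes `log(odds_ratio)` when
its exposure indicator is active, and the intercept is solved by bisection so
the marginal disorder prevalence matches `baseline_prevalence` exactly under
the configured exposure mixture. Defaults are study conditions, not tuning
knobs: three planted effects with odds ratios 3.0, 2.0, and 0.4; survey
completion probabilities 0.965/0.311/0.367 as observed in the motivating
cohort; missingness MCAR (optionally MAR).

Free-text answers (medication and product questions) emit the term label or
a branded synonym, with a 5% character-level typo rate, exercising the
lexical matcher the way real survey text would.

`standard_bundle(seed)` is the package's *a-priori* reference condition used
by the analysis scripts and the test suite: n = 2000 respondents, all three
surveys completed, 2% missingness, default planted effects. The size was
chosen (before any results were inspected) as the largest condition that
keeps a full two-arm run within a few minutes on one CPU.

## Limits of the emulation

The generator plants *marginal* pairwise effects only; it does not model
confounding structure, survey-block correlation, or longitudinal follow-up.
Free-text vocabulary is limited to labels and synonyms of generated terms,
so the lexical matcher's real-world failure modes (abbreviations, brand
portfolios) are only caricatured by the typo channel.

# Knowledge-graph arm

**Mapping.** A translation key maps each question to a predicate and either
a fixed CURIE (binary, ordinal), a value→CURIE map (categorical), or `MATCH`
(free text resolved by a deterministic lexical matcher over normalised
labels and synonyms; ambiguous strings map to nothing). Ordinal frequencies
binarise at > 0 for graph construction; non-use tokens ("none") and
unmatched strings are reported, never guessed.

**Graph.** Person nodes connect to term nodes by answer-derived edges; the
full subclass hierarchy and food-chemical supplemental links are merged.
Duplicate assertions collapse; self-loops and person-person edges are
invariant violations. The analysis uses the largest connected component,
matching the source study's handling of disconnected respondents.

**Split.** The 70/30 edge holdout must not change connectivity. Edges are
shuffled with a seeded RNG and streamed through a union-find: edges that
join two components form a spanning forest and always stay in training;
the remaining (cycle-closing) edges are individually removable, and the
first of them up to the target fraction become test edges. Removing the
whole test set therefore leaves the component count unchanged by
construction. On sparse graphs the achieved fraction falls below target
(down to zero on trees, with a warning) — an honest property of the
constraint, reported as `achieved_test_fraction`.

**Embedding.** First-order DeepWalk: `walks_per_node` uniform random walks
of `walk_length` from every node, treated as sentences for skip-gram with
negative sampling (window 5, five negatives from the unigram distribution
raised to 0.75, logistic loss, SGD with linear learning-rate decay).
Defaults: dimension 32, 10 walks of length 40, 5 epochs, learning rate
0.025. The trainer is a single-threaded C++ kernel with its own SplitMix64
RNG, so results are bit-reproducible for a seed regardless of R's RNG
state. Two numerical choices follow the reference word2vec implementation:
weights are single-precision floats and the sigmoid is a 4096-bin lookup
table over [-8, 8]; both are standard for SGNS, whose stochastic gradients
tolerate rounding far coarser than float precision. `epochs = 0` returns
the seeded initialisation, which the tests use as a no-training identity.

**Classifier.** Edge features are element-wise (Hadamard) products of
endpoint vectors (average, L1, L2 also available). A `ranger` probability
forest (501 trees, maximum depth 15, single-threaded, seeded) is trained on
training edges against an equal number of uniformly sampled non-edges —
sampled excluding *all* graph edges, so no held-out edge leaks in as a
negative. On graphs beyond desk scale the positives are a seeded uniform
subsample of `max_train_edges` (default 4000) training edges; on the
standard bundle this cuts forest fitting from ~30 s to ~12 s per fit at an
AUROC cost within one point, and `Inf` restores full-data training. Test
AUROC uses the rank (Mann-Whitney) statistic with ties counted one half.

**Prediction.** The forest is retrained on the full edge set with the
full-graph embedding, each disorder is scored as "source" against every
non-person term, and predictions with score > 0.8 are kept, sorted by
score.

## Behaviour of planted-signal recovery

An exposure attached to *most* disorder-positive persons (lift well above
2) is reliably recovered above the 0.8 threshold — the unit suite verifies
this on a 200-person fixture. Under the standard bundle's study conditions,
however, a planted odds ratio of 3.0 at 30% exposure prevalence and 10%
baseline prevalence yields a lift of only ~1.5. Skip-gram with k negatives
converges toward PMI − log k, which is *negative* for such a pair, so the
converged embedding does not place the pair at high similarity, and its
classifier score (~0.55 in profiling) sits well below the threshold while
structurally similar popular terms rank above it. This is a property of
similarity-based link prediction at desk scale, not an implementation
defect; the regression arm detects the same planted effect with adjusted
p-values far below 0.05.

# Regression arm

**Cohort and features.** Female respondents who completed all three surveys
form the cohort (each filter raises an error if it empties the table). The
wide table has one column per question CURIE: binaries 0/1, ordinals kept at
full 0-5 resolution, free text converted to an indicator of a lexical match
to the question's CURIE; repeated measurements collapse by maximum.

**Imputation.** `impute_missforest()` re-implements the missForest
algorithm (the package is not available in this environment): mean/mode
initialisation, columns visited in order of increasing missingness, one
random forest per column per sweep (fit on observed rows, predicted on
missing rows), stopping when the imputation-difference statistic first
increases — computed separately for continuous and categorical parts — and
returning the last table before degradation. Observed cells are never
altered; the unit suite asserts this cell-by-cell.

**Selection and fit.** Stage 1 retains features with nonzero coefficients
from an elastic-net logistic regression (alpha 0.5, seeded 5-fold CV,
lambda.min). Stage 2 fits a class-weighted probability forest on two thirds
of the rows and ranks retained features by mean AUROC drop over 20 seeded
permutations on the held-out third; positive-importance features proceed.
The final model is a joint ML logistic fit: odds ratio `exp(b)`, 95% CI
`exp(b ± 1.96 SE)`, Wald p-values, Bonferroni adjustment `min(1, m p)` with
m = number of tested features, per-feature VIF `1/(1 − R²)` from a linear
solve (`NA` when singular), and (quasi-)complete separation flagged and
reported with CI (0, ∞) rather than dropped.

# Comparison

`exact_match()` intersects, per disorder, the predicted destination CURIEs
with the regression features at adjusted p < alpha (default 0.05), by
strict CURIE identity. An ancestor-aware mode (off by default) also credits
matches where one side is an ontology ancestor of the other. Reports are
markdown plus per-disorder TSVs, with exact matches bolded.

# Problem sizes and reproducibility

All shipped analyses run on one CPU: the standard bundle's knowledge-graph
arm takes roughly 80 s (two embeddings at ~25 s each, two forest fits) and
the regression arm a few tens of seconds. These sizes are the package's own
desk-scale choices; the scientific claims they support are property-based
(oracle equivalences, seeded-replicate success rates), not numeric
reproductions of any specific cohort.

Every stochastic step takes an explicit integer seed, and the embedding
kernel's RNG is independent of R's stream. `analysis/01_simulate.R` through
`analysis/05_compare.R` regenerate the full results tree from seed 1;
`scripts/acceptance.R --seed S --out f.json` writes the headline quantities
for any seed.

# Open questions and decisions

* Whether cross-arm matches should be counted per disorder or jointly is
  ambiguous in the motivating design; the report prints both.
* Edge directionality carries no information here: storage is directed
  (subject → object) but walks, components, and candidate scoring treat the
  graph as undirected.
* The feature-selection fallback (univariate Wald filter at p < 0.1) exists
  for degenerate tables where the elastic net retains nothing; the default
  path is always the elastic net.

# Limitations

Desk-scale graphs (~2.3k nodes) are two orders of magnitude smaller than
production biomedical KGs; absolute AUROC values and score calibration do
not transfer. The comparison arm's exact-CURIE criterion is conservative:
semantically near-identical terms (sibling foods, parent classes) count as
misses unless ancestor-aware matching is enabled.
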