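# Correlated mixed-type feature table with known ground truth, for imputer
# tests. Ordinal columns are linear functions of a latent score plus noise;
# the binary column thresholds the same score, so columns are mutually
# informative.
make_table <- function(n = 300, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  tab <- data.frame(
    respondent_id = sprintf("P%04d", seq_len(n)),
    "FOODON:0000101" = round(pmin(5, pmax(0, 2.5 + 1.8 * z + rnorm(n, 0, 0.6)))),
    "FOODON:0000102" = round(pmin(5, pmax(0, 2.5 - 1.5 * z + rnorm(n, 0, 0.6)))),
    "ECTO:0000101" = as.numeric(z + rnorm(n, 0, 0.5) > 0),
    "HP:0000101" = as.numeric(z + rnorm(n, 0, 0.8) < 0.3),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  types <- c("FOODON:0000101" = "ordinal", "FOODON:0000102" = "ordinal",
             "ECTO:0000101" = "binary", "HP:0000101" = "binary")
  structure(tab, feature_types = types, raw = tab,
            class = c("feature_table", "data.frame"))
}

punch_holes <- function(tab, rate = 0.2, seed = 2) {
  set.seed(seed)
  for (f in feature_columns(tab)) {
    tab[[f]][runif(nrow(tab)) < rate] <- NA_real_
  }
  tab
}

nrmse <- function(imputed, truth, holes, cols) {
  num <- 0; den <- 0
  for (f in cols) {
    h <- holes[[f]]
    if (!any(h)) next
    num <- num + sum((imputed[[f]][h] - truth[[f]][h])^2)
    den <- den + sum((truth[[f]][h] - mean(truth[[f]]))^2)
  }
  sqrt(num / den)
}

test_that("cohort cleaning keeps female respondents who completed all surveys", {
  fx <- cohort_fixture()
  tab <- clean_cohort(fx$respondents, fx$responses, fx$questions, tiny_ontology())
  expect_equal(nrow(tab), 4)  # P01-P04: female with all three surveys
  expect_setequal(tab$respondent_id, sprintf("P%02d", 1:4))
  # one column per question CURIE
  expect_setequal(feature_columns(tab), fx$questions$curie)
  # ordinal kept at full resolution (not binarized)
  expect_true(any(tab[["FOODON:0000002"]] > 1, na.rm = TRUE))
  # binary coded 0/1
  expect_true(all(tab[["MONDO:0000002"]] %in% c(0, 1)))
  # free text becomes an indicator for the question's CURIE
  expect_true(all(tab[["CHEBI:0006375"]] %in% c(0, 1)))
})

test_that("degenerate cohorts raise the two filter errors", {
  fx <- cohort_fixture()
  males <- fx$respondents[fx$respondents$gender == "male", ]
  expect_error(clean_cohort(males, fx$responses, fx$questions, tiny_ontology()),
               "female-only filter")
  none_complete <- fx$respondents
  none_complete$completed_internal <- FALSE
  expect_error(clean_cohort(none_complete, fx$responses, fx$questions,
                            tiny_ontology()),
               "completion filter")
})

test_that("a complete table passes through the imputer unchanged", {
  tab <- make_table(100)
  out <- impute_missforest(tab, seed = 1)
  expect_equal(attr(out, "n_iterations"), 0L)
  expect_equal(as.data.frame(out), as.data.frame(tab), ignore_attr = TRUE)
})

test_that("observed cells are never modified by imputation", {
  truth <- make_table(200, seed = 3)
  tab <- punch_holes(truth, 0.2, seed = 4)
  out <- impute_missforest(tab, n_trees = 50, seed = 5)
  for (f in feature_columns(tab)) {
    obs <- !is.na(tab[[f]])
    expect_identical(out[[f]][obs], tab[[f]][obs])
    expect_false(anyNA(out[[f]]))
  }
  # deterministic under the seed
  out2 <- impute_missforest(tab, n_trees = 50, seed = 5)
  expect_identical(as.data.frame(out), as.data.frame(out2))
})

test_that("a deterministically dependent column is imputed near-exactly", {
  # y is a copy of x: a forest on x recovers the missing y cells
  set.seed(6)
  x <- as.numeric(sample(0:5, 200, replace = TRUE))
  tab <- structure(
    data.frame(respondent_id = sprintf("P%03d", 1:200),
               "FOODON:0000201" = x, "FOODON:0000202" = x,
               "ECTO:0000201" = as.numeric(x > 2),
               check.names = FALSE, stringsAsFactors = FALSE),
    feature_types = c("FOODON:0000201" = "ordinal",
                      "FOODON:0000202" = "ordinal",
                      "ECTO:0000201" = "binary"),
    class = c("feature_table", "data.frame"))
  holes <- sample(200, 40)
  tab[["FOODON:0000202"]][holes] <- NA_real_
  out <- impute_missforest(tab, n_trees = 100, seed = 7)
  # forest leaves average over the copy column, so cells land well within
  # half a level of the truth; mean imputation would miss by ~1.5 levels
  expect_lt(mean(abs(out[["FOODON:0000202"]][holes] - x[holes])), 0.5)
  expect_gt(mean(abs(mean(x) - x[holes])), 1)
})

test_that("forest imputation beats mean imputation on a correlated table", {
  truth <- make_table(400, seed = 8)
  tab <- punch_holes(truth, 0.2, seed = 9)
  holes <- lapply(tab, is.na)
  cont <- names(which(attr(tab, "feature_types") == "ordinal"))
  out <- impute_missforest(tab, n_trees = 50, seed = 10)
  mean_imp <- tab
  for (f in feature_columns(tab)) {
    mean_imp[[f]][holes[[f]]] <- mean(tab[[f]], na.rm = TRUE)
  }
  expect_lt(nrmse(out, truth, holes, cont), nrmse(mean_imp, truth, holes, cont))
})

test_that("fully missing columns are dropped with a warning", {
  tab <- punch_holes(make_table(80), 0.1, seed = 11)
  tab[["HP:0000101"]] <- NA_real_
  expect_warning(out <- impute_missforest(tab, n_trees = 20, seed = 1),
                 "HP:0000101")
  expect_false("HP:0000101" %in% names(out))
})

test_that("feature selection surfaces a strong planted predictor", {
  set.seed(12)
  n <- 400
  x_true <- rbinom(n, 1, 0.4)
  noise <- matrix(rbinom(n * 6, 1, 0.3), n, 6)
  logit <- -1.5 + log(6) * x_true
  y <- rbinom(n, 1, plogis(logit))
  tab <- data.frame(respondent_id = sprintf("P%04d", 1:n),
                    "MONDO:0000301" = as.numeric(y),
                    "ECTO:0000301" = as.numeric(x_true),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in 1:6) tab[[sprintf("ECTO:00003%02d", j + 1)]] <- noise[, j]
  sel <- select_features(tab, "MONDO:0000301", seed = 13)
  expect_true("ECTO:0000301" %in% sel$feature)
  expect_equal(sel$feature[1], "ECTO:0000301")  # top-ranked
  # univariate-filter stage-1 variant agrees on the planted feature
  sel2 <- select_features(tab, "MONDO:0000301", seed = 13, elastic_net = FALSE)
  expect_true("ECTO:0000301" %in% sel2$feature)
})

test_that("selection against a shuffled outcome retains little or nothing", {
  set.seed(14)
  n <- 300
  tab <- data.frame(respondent_id = sprintf("P%04d", 1:n),
                    "MONDO:0000301" = as.numeric(rbinom(n, 1, 0.3)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in 1:8) tab[[sprintf("ECTO:00004%02d", j)]] <- rbinom(n, 1, 0.4)
  sel <- suppressWarnings(select_features(tab, "MONDO:0000301", seed = 15))
  expect_lte(nrow(sel), 2)
})

test_that("Bonferroni adjustment equals the closed form and p.adjust", {
  expect_identical(bonferroni_adjust(c(0.9, 0.8), m = 5), c(1, 1))
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  p <- c(0.001, 0.02, 0.4, 0.9)
  expect_identical(bonferroni_adjust(p), pmin(1, length(p) * p))
  expect_identical(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("VIF matches a normal-equations oracle and flags collinearity", {
  set.seed(16)
  n <- 200
  a <- rnorm(n); b <- rnorm(n); c1 <- 0.8 * a + 0.6 * rnorm(n)
  tab <- data.frame(respondent_id = sprintf("P%03d", 1:n),
                    fa = a, fb = b, fc = c1)
  v <- compute_vif(tab, c("fa", "fb", "fc"))
  # oracle: R^2 via explicit normal equations
  oracle_vif <- function(y, Z) {
    Z1 <- cbind(1, Z)
    beta <- solve(t(Z1) %*% Z1, t(Z1) %*% y)
    r2 <- 1 - sum((y - Z1 %*% beta)^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }
  X <- as.matrix(tab[, c("fa", "fb", "fc")])
  for (j in 1:3) {
    expect_equal(unname(v[j]), oracle_vif(X[, j], X[, -j]), tolerance = 1e-6)
  }
  # independent column: VIF near 1; correlated pair: clearly above 1
  expect_lt(v["fb"], 1.1)
  expect_gt(v["fa"], 1.5)
  # duplicated column: not computable
  tab$fd <- tab$fa
  v2 <- compute_vif(tab, c("fa", "fb", "fd"))
  expect_true(is.na(v2["fa"]))
  expect_true(is.na(v2["fd"]))
})

test_that("single-predictor odds ratio equals the 2x2 closed form", {
  # cells: n11=30 exposed cases, n10=20 exposed controls,
  #        n01=35 unexposed cases, n00=90 unexposed controls
  x <- c(rep(1, 50), rep(0, 125))
  y <- c(rep(1, 30), rep(0, 20), rep(1, 35), rep(0, 90))
  tab <- data.frame(respondent_id = sprintf("P%03d", seq_along(x)),
                    "MONDO:0000501" = y, "ECTO:0000501" = x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  res <- fit_logistic(tab, "MONDO:0000501", "ECTO:0000501")
  expect_equal(res$odds_ratio, (30 * 90) / (20 * 35), tolerance = 1e-4)
  expect_false(res$separated)
  expect_gte(res$p_adjusted, res$p_raw)
})

test_that("the joint fit reproduces a plain glm to numerical precision", {
  set.seed(17)
  n <- 250
  tab <- data.frame(respondent_id = sprintf("P%03d", 1:n),
                    f1 = rbinom(n, 1, 0.4), f2 = as.numeric(sample(0:5, n, TRUE)),
                    f3 = rbinom(n, 1, 0.2))
  tab$yvar <- rbinom(n, 1, plogis(-1 + 0.8 * tab$f1 - 0.3 * tab$f2))
  res <- fit_logistic(tab, "yvar", c("f1", "f2", "f3"))
  ref <- stats::glm(yvar ~ f1 + f2 + f3, data = tab, family = stats::binomial())
  expect_equal(res$odds_ratio, unname(exp(stats::coef(ref)[2:4])),
               tolerance = 1e-6)
  expect_equal(res$standard_error,
               unname(stats::coef(summary(ref))[2:4, 2]), tolerance = 1e-6)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  # CI endpoints are exp(b +/- 1.96 SE)
  expect_equal(res$ci_low,
               unname(exp(stats::coef(ref)[2:4] - 1.96 * stats::coef(summary(ref))[2:4, 2])),
               tolerance = 1e-6)
})

test_that("quasi-complete separation is flagged and reported with unbounded CIs", {
  set.seed(18)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  sep <- ifelse(y == 1, rbinom(n, 1, 0.3), 0)  # exposure only among cases
  tab <- data.frame(respondent_id = sprintf("P%03d", 1:n),
                    yv = y, sep = sep, other = rbinom(n, 1, 0.5))
  res <- fit_logistic(tab, "yv", c("sep", "other"))
  i <- match("sep", res$feature)
  expect_true(res$separated[i])
  expect_equal(res$ci_low[i], 0)
  expect_equal(res$ci_high[i], Inf)
  # the clean covariate is untouched by the flag
  expect_false(res$separated[match("other", res$feature)])
})

test_that("prevalence and missingness statistics come from the raw table", {
  truth <- make_table(150, seed = 19)
  tab <- punch_holes(truth, 0.15, seed = 20)
  attr(tab, "raw") <- tab
  imp <- impute_missforest(tab, n_trees = 30, seed = 21)
  feats <- setdiff(feature_columns(imp), "HP:0000101")
  res <- fit_logistic(imp, "HP:0000101", feats, raw_table = tab)
  for (j in seq_along(feats)) {
    f <- feats[j]
    expect_equal(res$missingness_rate[j], mean(is.na(tab[[f]])))
    expect_equal(res$mean_prevalence[j], mean(tab[[f]], na.rm = TRUE))
  }
  expect_true(any(res$missingness_rate > 0))
})
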