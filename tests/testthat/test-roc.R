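test_that("perfect separation gives AUC 1 and Youden J = 1 at the gap midpoint", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, 1)
  cut <- youden_optimal(r)
  expect_equal(cut$youden, 1)
  expect_equal(cut$threshold, 6.5)   # midpoint of the separating gap
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
})

test_that("null scores give AUC near 1/2 and constant scores give J = 0", {
  set.seed(55)
  scores <- rnorm(4000)
  labels <- rbinom(4000, 1, 0.5)
  r <- roc_curve(scores, labels, direction = "greater")
  expect_lt(abs(r$auc - 0.5), 0.03)

  rc <- roc_curve(rep(1, 10), rep(c(0, 1), 5), direction = "greater")
  expect_equal(youden_optimal(rc)$youden, 0, tolerance = 1e-12)
})

test_that("trapezoidal AUC equals the rank-statistic form, with and without ties", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    scores <- sample(1:8, n, replace = TRUE)        # heavy ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))        # both classes present
    r <- roc_curve(scores, labels, direction = "greater")
    expect_equal(r$auc, auc_rank_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  cohort <- generate_cohort(default_cohort_spec(), seed = 8)
  r <- roc_curve(cohort$aptt, cohort$group, direction = "greater")
  ref <- pROC::roc(cohort$group, cohort$aptt, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms and flips with direction", {
  set.seed(66)
  scores <- rlnorm(120)
  labels <- rbinom(120, 1, plogis(log(scores)))
  r <- roc_curve(scores, labels, direction = "greater")
  expect_equal(roc_curve(log(scores), labels, direction = "greater")$auc, r$auc)
  expect_equal(roc_curve(scores^3, labels, direction = "greater")$auc, r$auc)

  rflip <- roc_curve(-scores, labels, direction = "greater")
  expect_equal(rflip$auc, 1 - r$auc, tolerance = 1e-12)

  # auto-direction picks the orientation with AUC >= 0.5 and records the flip
  rauto <- roc_curve(-scores, labels)
  expect_gte(rauto$auc, 0.5)
  expect_equal(rauto$direction, "less")
  expect_true(rauto$direction_flipped)
})

test_that("Youden argmax agrees with exhaustive threshold evaluation", {
  set.seed(77)
  for (i in 1:20) {
    scores <- round(rnorm(12), 1)
    labels <- c(0, 1, rbinom(10, 1, 0.5))
    r <- roc_curve(scores, labels, direction = "greater")
    cut <- youden_optimal(r)
    j_all <- r$sensitivity + r$specificity - 1
    expect_equal(cut$youden, max(j_all), tolerance = 1e-12)
    expect_true(all(cut$youden >= j_all - 1e-12))
    # tie-break: no other maximiser has higher sensitivity
    at_max <- which(j_all >= max(j_all) - 1e-12)
    expect_gte(cut$sensitivity, max(r$sensitivity[at_max]) - 1e-12)
  }
})

test_that("single-class labels and invalid scores are rejected", {
  expect_error(roc_curve(1:5, rep(1, 5)), "single-class")
  expect_error(roc_curve(c(1, NA, 3), c(0, 1, 1)), "finite")
})

test_that("stratified rates reproduce the published display convention", {
  fx <- reference_fixtures()
  rt <- stratified_rates(fx$strata)
  expect_equal(rt$rate, c(95.12, 95.23, 83, 60.97, 81.67, 50.79))
  # half-to-even rounding is available and differs where truncation bit
  rt2 <- stratified_rates(fx$strata, mode = "round")
  expect_equal(rt2$rate[4], 60.98)

  expect_equal(stratified_rates(data.frame(stratum = "none", n = 10, k = 0))$rate, 0)
  expect_error(stratified_rates(data.frame(stratum = "bad", n = 0, k = 0)), "n = 0")
  expect_error(stratified_rates(data.frame(stratum = "bad", n = 3, k = 5)), "k <= n")
})

test_that("risk-score AUC dominates single covariates under a known mechanism", {
  # with a multivariate logistic mechanism the true linear predictor is the
  # optimal score; its empirical AUC should beat each single covariate in
  # most replicates (small-n violations are counted, not hidden)
  v1 <- variable_spec("x1", "normal", pooled = list(mean = 3, sd = 1))
  v2 <- variable_spec("x2", "normal", pooled = list(mean = 3, sd = 1))
  spec <- cohort_spec(list(v1, v2), 100, 100,
                      mechanism = list(intercept = -4.5,
                                       coef = c(x1 = 1.0, x2 = 0.5)))
  wins <- vapply(1:30, function(s) {
    cohort <- generate_cohort(spec, seed = 300 + s)
    if (length(unique(cohort$group)) < 2) return(NA)
    lp <- 1.0 * cohort$x1 + 0.5 * cohort$x2
    a_lp <- roc_curve(lp, cohort$group, direction = "greater")$auc
    a1 <- roc_curve(cohort$x1, cohort$group, direction = "greater")$auc
    a2 <- roc_curve(cohort$x2, cohort$group, direction = "greater")$auc
    a_lp >= max(a1, a2)
  }, TRUE)
  expect_gte(mean(wins, na.rm = TRUE), 0.8)
})
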