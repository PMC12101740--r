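test_that("fixed-margins generation yields exact group sizes and is deterministic", {
  spec <- default_cohort_spec()
  cohort <- generate_cohort(spec, seed = 123)
  expect_equal(nrow(cohort), 194)
  expect_equal(sum(cohort$group == 0), 57)
  expect_equal(sum(cohort$group == 1), 137)
  expect_false(anyNA(cohort))

  cohort2 <- generate_cohort(spec, seed = 123)
  expect_identical(cohort, cohort2)
  cohort3 <- generate_cohort(spec, seed = 124)
  expect_false(identical(cohort$aptt, cohort3$aptt))
})

test_that("binary prevalences are unbiased across replicate seeds", {
  # binomial sampling oracle: mean simulated CKD prevalence in the
  # overexposed group across seeds stays within 3 Monte-Carlo SEs of 0.2773
  spec <- default_cohort_spec()
  n_rep <- 500
  prev <- vapply(seq_len(n_rep), function(s) {
    cohort <- generate_cohort(spec, seed = s)
    mean(cohort$ckd[cohort$group == 1])
  }, 1)
  p0 <- 0.2773
  se <- sqrt(p0 * (1 - p0) / (137 * n_rep))
  expect_lt(abs(mean(prev) - p0), 3 * se)
})

test_that("continuous margins converge to the specified summaries at large n", {
  spec <- cohort_spec(
    list(variable_spec("aptt", "lognormal",
                       compliant = list(median = 32.70, q1 = 29.15, q3 = 37.20),
                       overexposed = list(median = 37.00, q1 = 33.95, q3 = 43.60)),
         variable_spec("age", "normal",
                       compliant = list(mean = 59.79, sd = 13.54),
                       overexposed = list(mean = 65.55, sd = 14.45))),
    n_compliant = 10000, n_overexposed = 10000)
  cohort <- generate_cohort(spec, seed = 99)
  g1 <- cohort$group == 1
  expect_equal(median(cohort$aptt[g1]), 37.00, tolerance = 0.02)
  p <- lognormal_from_quartiles(37.00, 33.95, 43.60)
  expect_equal(unname(quantile(cohort$aptt[g1], 0.25)),
               qlnorm(0.25, p$meanlog, p$sdlog), tolerance = 0.02)
  expect_equal(mean(cohort$age[!g1]), 59.79, tolerance = 0.02)
  expect_equal(sd(cohort$age[!g1]), 13.54, tolerance = 0.05)
  expect_true(all(cohort$age > 0))
})

test_that("log-normal quartile matching is exact in closed form", {
  # asymmetric summary: median and interquartile ratio reproduced exactly
  p <- lognormal_from_quartiles(36.35, 32.15, 42.20)
  q <- qlnorm(c(0.25, 0.5, 0.75), p$meanlog, p$sdlog)
  expect_equal(q[2], 36.35, tolerance = 1e-9)
  expect_equal(q[3] / q[1], 42.20 / 32.15, tolerance = 1e-9)

  # log-symmetric summary: all three quartiles reproduced exactly
  p_sym <- lognormal_from_quartiles(10, 5, 20)
  expect_equal(qlnorm(c(0.25, 0.5, 0.75), p_sym$meanlog, p_sym$sdlog),
               c(5, 10, 20), tolerance = 1e-9)

  expect_equal(lognormal_from_quartiles(1, 1, 1)$sdlog, 0)

  p2 <- lognormal_from_quartiles(10, 5, 20)
  expect_equal(p2$meanlog, log(10))
  expect_equal(p2$sdlog, log(4) / (2 * qnorm(0.75)))

  expect_error(lognormal_from_quartiles(10, -1, 20), "positive")
  expect_error(lognormal_from_quartiles(10, 12, 20), "q1 <= median")
})

test_that("spec validation names the offending field", {
  expect_error(variable_spec("x", "normal", compliant = list(mean = 1, sd = 0),
                             overexposed = list(mean = 1, sd = 1)),
               "sd must be > 0 for 'x'")
  expect_error(variable_spec("x", "binary", compliant = list(prev = 1.2),
                             overexposed = list(prev = 0.5)),
               "prevalence")
  v <- variable_spec("x", "binary", compliant = list(prev = 0.2),
                     overexposed = list(prev = 0.5))
  expect_error(cohort_spec(list(v), 0, 10), "positive")
  expect_error(cohort_spec(list(v, v), 10, 10), "duplicate")
  expect_error(cohort_spec(list(v), 10, 10,
                           mechanism = list(intercept = 0, coef = c(zz = 1))),
               "unknown variable")
})

test_that("mechanism mode labels follow the logistic model", {
  v1 <- variable_spec("x1", "normal", pooled = list(mean = 0.001, sd = 1))
  v2 <- variable_spec("b1", "binary", pooled = list(prev = 0.4))
  spec <- cohort_spec(list(v1, v2), 100, 100,
                      mechanism = list(intercept = -0.2, coef = c(x1 = 1.5, b1 = 0.8)))
  cohort <- generate_cohort(spec, seed = 5)
  expect_equal(nrow(cohort), 200)
  expect_true(all(cohort$group %in% 0:1))
  # strong positive coefficient: mean x1 must be higher among cases
  expect_gt(mean(cohort$x1[cohort$group == 1]), mean(cohort$x1[cohort$group == 0]))
})

test_that("cohort CSV and spec YAML round-trips preserve content", {
  spec <- default_cohort_spec()
  cohort <- generate_cohort(spec, seed = 7)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, csv)
  back <- read_cohort(csv)
  expect_equal(back$aptt, cohort$aptt, tolerance = 1e-12)
  expect_identical(back$group, cohort$group)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, yml)
  spec2 <- read_cohort_spec(yml)
  expect_identical(generate_cohort(spec2, seed = 7)$aptt, cohort$aptt)
})
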