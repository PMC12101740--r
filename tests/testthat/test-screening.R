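test_that("identical groups give null statistics", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_continuous(x, x, mode = "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_false(r$selected)

  r2 <- compare_binary(10, 10, 10, 10)
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-12)
})

test_that("small-sample rank-sum p matches exact enumeration", {
  r <- compare_continuous(c(1, 2, 3), c(4, 5, 6), mode = "ranksum")
  expect_equal(unname(r$statistic), 0)      # U = 0: complete separation of ranks
  # brute force over all choose(6,3) = 20 rank assignments:
  # P(U <= 0) = 1/20 each tail, two-sided p = 2/20
  combs <- utils::combn(6, 3)
  u_all <- apply(combs, 2, function(idx) sum(rank(1:6)[idx]) - 3 * 4 / 2)
  p_exact <- 2 * mean(u_all <= 0)
  expect_equal(r$p, p_exact)
  expect_equal(r$p, 0.1)
})

test_that("rank-sum p is invariant to monotone transforms of the pooled data", {
  set.seed(88)
  x <- rlnorm(25); y <- rlnorm(30, meanlog = 0.5)
  p1 <- compare_continuous(x, y, mode = "ranksum")$p
  for (f in list(log, sqrt, function(v) v^3)) {
    expect_equal(compare_continuous(f(x), f(y), mode = "ranksum")$p, p1)
  }
  # label swap symmetry (t and rank-sum)
  expect_equal(compare_continuous(y, x, mode = "ranksum")$p, p1)
  expect_equal(compare_continuous(y, x, mode = "t")$p,
               compare_continuous(x, y, mode = "t")$p)
})

test_that("binary comparison picks Fisher at low expected counts and matches the oracle", {
  # comorbidity counts: 3/57 compliant vs 38/137 overexposed
  r <- compare_binary(3, 54, 38, 99)
  # the rule decision must match the expected-count criterion
  expected <- outer(c(57, 137), c(41, 153)) / 194
  if (any(expected < 5)) {
    expect_equal(r$test, "Fisher exact")
  } else {
    expect_equal(r$test, "chi-square (Yates)")
  }
  expect_lt(r$p, 0.001)
  # direction: overexposure enriched among comorbid patients
  expect_gt(38 / 137, 3 / 57)

  rf <- compare_binary(1, 1, 1, 1, test = "fisher")
  expect_equal(rf$p, 1)

  expect_error(compare_binary(0, 0, 3, 4), "margin")
  expect_error(compare_binary(1.5, 1, 1, 1), "integers")
})

test_that("forced-Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(19)
  for (i in 1:50) {
    repeat {
      cells <- as.integer(rmultinom(1, sample(8:40, 1), rep(1 / 4, 4)))
      tab <- matrix(cells, 2, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    r <- compare_binary(cells[1], cells[2], cells[3], cells[4], test = "fisher")
    expect_equal(r$p, fisher_p_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("screen_cohort gates at alpha, respects kinds, and keeps spec order", {
  spec <- default_cohort_spec()
  cohort <- generate_cohort(spec, seed = 42)
  sc <- screen_cohort(cohort)
  expect_equal(sc$variable, names(spec$variables))
  expect_true(all(sc$selected == (sc$p < 0.05)))
  expect_equal(sc$test[sc$variable == "age"], "t (Welch)")
  expect_equal(sc$test[sc$variable == "aptt"], "Wilcoxon rank-sum")
  expect_true(grepl("chi-square|Fisher", sc$test[sc$variable == "ckd"]))

  # alpha = 1 selects everything
  sc1 <- screen_cohort(cohort, alpha = 1)
  expect_true(all(sc1$selected))

  expect_error(screen_cohort(cohort, alpha = 0), "alpha")
  expect_error(screen_cohort(as.data.frame(cohort)[, -2],
                             specs = spec$variables), "not present")
})

test_that("a strong true effect is detected in nearly every replicate", {
  # power oracle: CKD prevalence 5.26% vs 27.73% at n = 57/137 is a large
  # effect; the screening gate must select it in >= 95% of seeds
  spec <- default_cohort_spec()
  hits <- vapply(1:100, function(s) {
    cohort <- generate_cohort(spec, seed = 1000 + s)
    sc <- screen_cohort(cohort)
    sc$selected[sc$variable == "ckd"]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("screening results serialise to CSV and JSON", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 3)
  sc <- screen_cohort(cohort)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_screening(sc, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$p, sc$p, tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  write_screening(sc, js)
  expect_equal(vapply(jsonlite::read_json(js), `[[`, "", "variable"),
               sc$variable)
})
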