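test_that("column-normalisation weights reproduce the published scheme-layer vector", {
  w <- priority_column_norm(scheme_matrix())
  expect_equal(round(unname(w), 4), c(0.7671, 0.0900, 0.1429))
  expect_equal(sum(w), 1, tolerance = 1e-9)

  # symmetry: an all-ones matrix gives uniform weights
  ones <- judgment_matrix(matrix(1, 3, 3))
  expect_equal(unname(priority_column_norm(ones)), rep(1 / 3, 3))

  # analytic fixed point: a consistent matrix returns its generating weights
  w0 <- c(0.6, 0.3, 0.1)
  expect_equal(unname(priority_column_norm(consistent_matrix(w0))), w0,
               tolerance = 1e-12)
})

test_that("eigenvector weights match a high-precision eigen decomposition", {
  w0 <- c(0.6, 0.3, 0.1)
  expect_equal(unname(priority_eigen(consistent_matrix(w0))), w0,
               tolerance = 1e-9, ignore_attr = TRUE)

  w <- priority_eigen(scheme_matrix(), tol = 1e-12)
  expect_equal(round(as.numeric(w), 4), c(0.7732, 0.0877, 0.1392))
  # cross-check against base eigen()
  ev <- eigen(as.matrix(scheme_matrix()))
  ref <- Re(ev$vectors[, 1]); ref <- ref / sum(ref)
  expect_equal(as.numeric(w), ref, tolerance = 1e-9)

  one <- judgment_matrix(list(1))
  expect_equal(as.numeric(priority_eigen(one)), 1)

  expect_error(priority_eigen(scheme_matrix(), tol = 0, max_iter = 3L),
               "did not converge")
})

test_that("lambda-max estimator matches exact arithmetic and the consistent case", {
  m <- scheme_matrix()
  lam <- estimate_lambda_max(m, priority_column_norm(m))
  expect_equal(round(lam, 4), 3.0544)

  w0 <- c(0.5, 0.3, 0.2)
  expect_equal(estimate_lambda_max(consistent_matrix(w0), w0), 3, tolerance = 1e-12)

  ones <- judgment_matrix(matrix(1, 4, 4))
  expect_equal(estimate_lambda_max(ones, rep(0.25, 4)), 4)

  expect_error(estimate_lambda_max(m, c(1, 0, 1)), "not strictly positive")
})

test_that("consistency index follows (lambda - n)/(n - 1) with clamping", {
  expect_equal(round(consistency_index(3.0544, 3), 4), 0.0272)
  expect_equal(consistency_index(5, 5), 0)
  expect_equal(consistency_index(4.27, 4), 0.09)
  expect_equal(consistency_index(1.7, 1), 0)           # order 1: defined 0
  expect_equal(consistency_index(3 - 1e-9, 3), 0)      # tiny negative clamped
  expect_error(consistency_index(2.9, 3), "inconsistent input")
})

test_that("consistency ratio applies the CR < 0.10 acceptance rule", {
  cr <- consistency_ratio(0.0272, 0.58)
  expect_equal(round(cr$cr, 4), 0.0469)
  expect_true(cr$acceptable)

  cr0 <- consistency_ratio(0, 1.12)
  expect_equal(cr0$cr, 0)
  expect_true(cr0$acceptable)

  crbad <- consistency_ratio(0.12, 0.9)
  expect_equal(round(crbad$cr, 4), 0.1333)
  expect_false(crbad$acceptable)

  expect_error(consistency_ratio(0.1, 0), "undefined")
})

test_that("random index: table lookup, degenerate small orders, simulation determinism", {
  expect_equal(random_index(3), 0.58)
  expect_equal(random_index(4), 0.90)
  expect_equal(random_index(1), 0)
  expect_equal(random_index(2, mode = "simulated", reps = 10, seed = 1), 0)
  expect_error(random_index(10), "simulated")

  r1 <- random_index(3, reps = 200, seed = 7, mode = "simulated")
  r2 <- random_index(3, reps = 200, seed = 7, mode = "simulated")
  expect_identical(r1, r2)
  expect_gt(r1, 0)

  # moderate-rep simulation already lands near the tabulated value
  r <- random_index(3, reps = 5000, seed = 11, mode = "simulated")
  expect_lt(abs(r - 0.58), 0.1)
})

test_that("analyze_matrix assembles weights and the full consistency report", {
  a <- analyze_matrix(scheme_matrix())
  expect_equal(round(unname(a$weights), 4), c(0.7671, 0.0900, 0.1429))
  expect_equal(round(a$report$ci, 4), 0.0272)
  expect_equal(round(a$report$cr, 4), 0.0469)
  expect_true(a$report$acceptable)

  cons <- judgment_matrix(consistent_matrix(c(0.4, 0.3, 0.2, 0.1)))
  a4 <- analyze_matrix(cons)
  expect_equal(a4$report$ci, 0, tolerance = 1e-9)
  expect_equal(a4$report$cr, 0, tolerance = 1e-9)
  expect_true(a4$report$acceptable)

  # perturb one cell of a consistent matrix until CR crosses 0.10
  A <- consistent_matrix(c(0.5, 0.3, 0.2))
  A[1, 2] <- 9; A[2, 1] <- 1 / 9
  bad <- analyze_matrix(judgment_matrix(A), method = "eigen")
  expect_gt(bad$report$cr, 0.10)
  expect_false(bad$report$acceptable)
})

test_that("both weight methods are normalised and recover consistent matrices", {
  set.seed(402)
  for (n in 3:5) {
    for (rep in 1:25) {
      A <- judgment_matrix(random_saaty_matrix(n), validate = FALSE)
      for (f in list(priority_column_norm, priority_eigen)) {
        w <- f(A)
        expect_true(all(w >= 0))
        expect_equal(sum(w), 1, tolerance = 1e-9)
      }
      w0 <- as.numeric(prop.table(runif(n, 0.05, 1)))
      C <- consistent_matrix(w0)
      expect_equal(unname(priority_column_norm(C)), w0, tolerance = 1e-9)
      expect_equal(as.numeric(priority_eigen(C)), w0, tolerance = 1e-9)
      expect_equal(estimate_lambda_max(C, w0), n, tolerance = 1e-9)
    }
  }
})

test_that("rank_items orders by descending weight and flags ties", {
  r <- rank_items(c(APTT = 0.0584, OI = 0.1899, CHF = 0.1614, CKD = 0.5902))
  expect_equal(as.character(r), c("CKD", "OI", "CHF", "APTT"))
  expect_false(attr(r, "ties"))

  r2 <- rank_items(c(dose = 0.7671, interval = 0.09, infusion = 0.1429))
  expect_equal(as.character(r2), c("dose", "infusion", "interval"))

  ru <- rank_items(c(a = 1 / 3, b = 1 / 3, c = 1 / 3))
  expect_equal(as.character(ru), c("a", "b", "c"))  # input order kept
  expect_true(attr(ru, "ties"))
})
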