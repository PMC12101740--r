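# Priority-weight extraction and consistency analytics for judgment matrices.

as_jm_matrix <- function(m) {
  if (inherits(m, "judgment_matrix")) return(as.matrix(m))
  if (is.matrix(m) && is.numeric(m)) return(m)
  stop("expected a judgment_matrix or a numeric matrix", call. = FALSE)
}

#' Priority weights by column normalisation with row averaging
#'
#' Divides each column of the judgment matrix by its column sum and averages
#' across rows. This is the arithmetic-mean (normalised-column-sum) weighting
#' scheme; for a fully consistent matrix `a_ij = w_i / w_j` it recovers `w`
#' exactly, and it is the package default because it reproduces the reference
#' scheme-layer weights (0.7671, 0.0900, 0.1429) to 4 decimal places.
#'
#' @param m A [judgment_matrix] (or plain positive numeric matrix).
#' @return Named numeric vector of weights summing to 1.
#' @seealso [priority_eigen()] for the principal-eigenvector alternative.
#' @export
priority_column_norm <- function(m) {
  A <- as_jm_matrix(m)
  w <- rowMeans(sweep(A, 2, colSums(A), "/"))
  names(w) <- colnames(A) %||% paste0("item", seq_len(nrow(A)))
  w
}

#' Priority weights by the principal-eigenvector method
#'
#' Computes the normalised principal (Perron) eigenvector of the judgment
#' matrix by power iteration. The classical eigenvector weighting of the
#' analytic hierarchy process; it generally differs from
#' [priority_column_norm()] on inconsistent matrices.
#'
#' @param m A [judgment_matrix] (or positive numeric matrix).
#' @param tol Convergence tolerance: iteration stops when successive
#'   normalised iterates differ by less than `tol` in max norm. Default 1e-12.
#' @param max_iter Maximum number of power iterations (default 1000).
#' @return Named numeric vector of weights summing to 1, with attribute
#'   `lambda_max` (the converged principal eigenvalue estimate) and
#'   `iterations`.
#' @export
priority_eigen <- function(m, tol = 1e-12, max_iter = 1000L) {
  A <- as_jm_matrix(m)
  n <- nrow(A)
  w <- rep(1 / n, n)
  lam <- n
  for (it in seq_len(max_iter)) {
    v <- drop(A %*% w)
    lam <- sum(v)
    v <- v / lam
    if (max(abs(v - w)) < tol) {
      names(v) <- colnames(A) %||% paste0("item", seq_len(n))
      attr(v, "lambda_max") <- mean(drop(A %*% v) / v)
      attr(v, "iterations") <- it
      return(v)
    }
    w <- v
  }
  stop(sprintf(paste0("power iteration did not converge in %d iterations ",
                      "(last max-norm change on record exceeds tol = %g); ",
                      "last iterate: %s"),
               max_iter, tol, paste(signif(w, 6), collapse = ", ")),
       call. = FALSE)
}

#' Estimate the maximum eigenvalue from a weight vector
#'
#' The lambda-max estimator used by the consistency index: the average over
#' rows of `(A w)_i / w_i`. For the exact principal eigenvector this equals
#' the principal eigenvalue; for any other positive weight vector it is the
#' Rayleigh-style row average the AHP consistency check is built on.
#'
#' @param m A [judgment_matrix] (or positive numeric matrix).
#' @param w Strictly positive weight vector, same length as the matrix order.
#' @return The lambda-max estimate (a scalar `>= n` at the true eigenvector).
#' @export
estimate_lambda_max <- function(m, w) {
  A <- as_jm_matrix(m)
  w <- as.numeric(w)
  stopifnot(length(w) == nrow(A))
  if (any(w <= 0)) {
    stop(sprintf("weight %d is not strictly positive (division by zero)",
                 which(w <= 0)[1]), call. = FALSE)
  }
  mean(drop(A %*% w) / w)
}

#' Consistency index of a judgment matrix
#'
#' `CI = (lambda_max - n) / (n - 1)` for order `n >= 2`; defined 0 for
#' `n <= 1`. Tiny negative values (down to -1e-9, floating-point noise around
#' a perfectly consistent matrix) are clamped to 0.
#'
#' @param lambda_max Lambda-max estimate, see [estimate_lambda_max()].
#' @param n Matrix order.
#' @return The consistency index (non-negative scalar).
#' @export
consistency_index <- function(lambda_max, n) {
  stopifnot(n >= 1)
  if (n <= 1) return(0)
  if (lambda_max < n - 1e-6) {
    stop(sprintf("lambda_max (%g) below matrix order (%d): inconsistent input",
                 lambda_max, n), call. = FALSE)
  }
  ci <- (lambda_max - n) / (n - 1)
  if (ci < 0) ci <- 0
  ci
}

# Saaty's tabulated mean random consistency index for orders 1..9.
ri_table_values <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

# Vectorised power iteration for `reps` random reciprocal matrices of order n.
# `cells` is a reps x n(n-1)/2 matrix of upper-triangle entries (row-major).
# Returns the principal eigenvalue of each matrix.
lambda_max_batch <- function(cells, n, tol = 1e-10, max_iter = 500L) {
  reps <- nrow(cells)
  # A[[i]][[j]] is the reps-long vector of (i,j) entries.
  A <- matrix(vector("list", n * n), n, n)
  k <- 0L
  for (i in seq_len(n)) A[[i, i]] <- rep(1, reps)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      A[[i, j]] <- cells[, k]
      A[[j, i]] <- 1 / cells[, k]
    }
  }
  w <- matrix(1 / n, reps, n)
  lam <- rep(NA_real_, reps)
  for (it in seq_len(max_iter)) {
    v <- matrix(0, reps, n)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + A[[i, j]] * w[, j]
      v[, i] <- acc
    }
    lam <- rowSums(v)
    v <- v / lam
    if (max(abs(v - w)) < tol) break
    w <- v
  }
  # Row-averaged Rayleigh quotient at the converged vector.
  num <- matrix(0, reps, n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + A[[i, j]] * v[, j]
    num[, i] <- acc
  }
  rowMeans(num / v)
}

#' Random consistency index
#'
#' The mean consistency index of random Saaty reciprocal matrices of order
#' `n`, used as the denominator of the consistency ratio. Two sources:
#' `"table"` returns the standard tabulated values
#' (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45 for n = 1..9);
#' `"simulated"` draws `reps` random positive reciprocal matrices — each
#' upper-triangle cell uniform over the 17-element Saaty set, lower triangle
#' reciprocal, unit diagonal — computes each principal eigenvalue by power
#' iteration, and returns `mean(lambda_max - n) / (n - 1)`.
#'
#' @param n Matrix order (`n >= 1`).
#' @param reps Number of random matrices in simulated mode (default 500).
#' @param seed Optional RNG seed for simulated mode.
#' @param mode `"table"` (default) or `"simulated"`.
#' @return The random index (scalar, 0 for `n <= 2` in both modes).
#' @export
random_index <- function(n, reps = 500L, seed = NULL,
                         mode = c("table", "simulated")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (n <= 2) return(0)
  if (mode == "table") {
    if (n > 9) {
      stop("tabulated random index only available for n <= 9; use mode = \"simulated\"",
           call. = FALSE)
    }
    return(ri_table_values[n])
  }
  stopifnot(reps >= 1)
  k <- n * (n - 1) / 2
  saaty_vals <- saaty_num / saaty_den
  with_seed(seed, {
    cells <- matrix(saaty_vals[sample.int(17L, reps * k, replace = TRUE)],
                    nrow = reps, ncol = k)
    lam <- lambda_max_batch(cells, n)
    mean(lam - n) / (n - 1)
  })
}

#' Consistency ratio
#'
#' `CR = CI / RI`; a judgment matrix is conventionally accepted when
#' `CR < 0.10`. For orders 1 and 2 the random index is 0 and any reciprocal
#' matrix is consistent, so CR is defined as 0 (acceptable).
#'
#' @param ci Consistency index.
#' @param ri Random index (`>= 0`).
#' @return List with `cr` and logical `acceptable`.
#' @export
consistency_ratio <- function(ci, ri) {
  stopifnot(ri >= 0)
  if (ri == 0) {
    if (ci > 1e-12) {
      stop("consistency ratio undefined: RI = 0 with CI > 0", call. = FALSE)
    }
    return(list(cr = 0, acceptable = TRUE))
  }
  cr <- ci / ri
  list(cr = cr, acceptable = cr < 0.10)
}

new_consistency_report <- function(lambda_max, ci, ri, cr, acceptable, n) {
  structure(list(lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
                 acceptable = acceptable, n = n),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency report (order %d)\n", x$n))
  cat(sprintf("  lambda_max = %.4f   CI = %.4f   RI = %.4f   CR = %.4f\n",
              x$lambda_max, x$ci, x$ri, x$cr))
  cat(sprintf("  %s (CR %s 0.10)\n",
              if (x$acceptable) "acceptable" else "NOT acceptable",
              if (x$acceptable) "<" else ">="))
  invisible(x)
}

#' Single-level analysis of a judgment matrix
#'
#' Extracts priority weights by the chosen method and assembles the full
#' consistency report: lambda-max at those weights, CI, RI (tabulated or
#' simulated) and CR with the CR < 0.10 acceptance flag. This is the
#' "hierarchical single ranking and consistency test" of a one-level AHP.
#'
#' @param m A [judgment_matrix].
#' @param method `"column_norm"` (default) or `"eigen"`.
#' @param ri_mode `"table"` (default) or `"simulated"`.
#' @param seed Seed for simulated RI.
#' @param reps Replicates for simulated RI (default 500).
#' @return List with `weights` (a named priority vector) and `report`
#'   (a `consistency_report`).
#' @examples
#' m <- judgment_matrix(list(c(1, 7, 7), c("1/7", 1, "1/2"), c("1/7", 2, 1)))
#' analyze_matrix(m)
#' @export
analyze_matrix <- function(m, method = c("column_norm", "eigen"),
                           ri_mode = c("table", "simulated"),
                           seed = NULL, reps = 500L) {
  method <- match.arg(method)
  ri_mode <- match.arg(ri_mode)
  w <- switch(method,
              column_norm = priority_column_norm(m),
              eigen = priority_eigen(m))
  n <- length(w)
  lam <- estimate_lambda_max(m, w)
  ci <- consistency_index(lam, n)
  ri <- random_index(n, reps = reps, seed = seed, mode = ri_mode)
  crf <- if (n <= 2) list(cr = 0, acceptable = TRUE) else consistency_ratio(ci, ri)
  weights <- structure(as.numeric(w), names = names(w))
  list(weights = weights,
       report = new_consistency_report(lam, ci, ri, crf$cr, crf$acceptable, n))
}

#' Rank items by descending priority weight
#'
#' @param w Named numeric weight vector (a priority vector).
#' @return Character vector of labels in strictly descending weight order
#'   (ties keep input order), with attributes `ties` (logical: any ties
#'   present) and `tied_groups` (list of tied label groups, if any).
#' @examples
#' rank_items(c(APTT = 0.0584, OI = 0.1899, CHF = 0.1614, CKD = 0.5902))
#' @export
rank_items <- function(w) {
  stopifnot(is.numeric(w), !is.null(names(w)))
  ord <- order(-w)  # stable: ties keep input order
  out <- names(w)[ord]
  dup <- duplicated(w[ord]) | duplicated(w[ord], fromLast = TRUE)
  attr(out, "ties") <- any(dup)
  if (any(dup)) {
    attr(out, "tied_groups") <- split(out[dup], factor(w[ord][dup], levels = unique(w[ord][dup])))
  }
  out
}
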