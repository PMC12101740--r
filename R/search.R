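# Inverse search: which Saaty judgment matrices yield a given weight vector?
#
# Exists because published AHP analyses sometimes print the derived weights
# while the judgment matrix itself is lost or typographically corrupted; the
# search enumerates every Saaty reciprocal matrix of small order and keeps
# those whose weights round to the target.

#' Search for judgment matrices matching target weights
#'
#' Exhaustively enumerates all positive reciprocal matrices of order `n`
#' whose upper-triangle entries lie in the 17-element Saaty set, derives each
#' matrix's priority weights by the chosen method, and returns those whose
#' weights round to `target` at `tol_dp` decimal places. Enumeration is
#' deterministic (row-major over the upper triangle, Saaty values ascending);
#' an empty result is a valid, informative outcome.
#'
#' The search space has `17^(n(n-1)/2)` candidates, so only `n <= 4`
#' (24,137,569 matrices) is permitted; larger orders are refused.
#'
#' @param target Named (or unnamed) numeric vector of target weights summing
#'   to 1 (within 1e-6).
#' @param n Matrix order; must equal `length(target)` and be at most 4.
#' @param method `"column_norm"` (default) or `"eigen"`.
#' @param tol_dp Decimal places at which candidate weights must round to the
#'   target (default 4).
#' @param max_results Cap on the number of matrices returned (default 100);
#'   the total match count is always reported.
#' @return An object of class `jm_search`: list with `matches` (list of
#'   `judgment_matrix` objects, each carrying attributes `weights`, `ci` and
#'   `distance` = max-norm distance of its weights from the target, sorted by
#'   that distance), `n_matches` (total found), `n_enumerated`, `target`,
#'   `method`, `tol_dp`.
#' @examples
#' search_matrix_for_weights(c(0.5, 0.5), n = 2)
#' @export
search_matrix_for_weights <- function(target, n = length(target),
                                      method = c("column_norm", "eigen"),
                                      tol_dp = 4L, max_results = 100L) {
  method <- match.arg(method)
  stopifnot(length(target) == n, n >= 1)
  if (n > 4) {
    stop(sprintf(paste0("order %d needs 17^%d matrix evaluations; ",
                        "exhaustive search is limited to n <= 4"),
                 n, n * (n - 1) / 2), call. = FALSE)
  }
  if (abs(sum(target) - 1) > 1e-6) {
    stop("target weights must sum to 1", call. = FALSE)
  }
  labels <- names(target) %||% paste0("item", seq_len(n))
  target <- as.numeric(target)

  if (n == 1) {
    m <- judgment_matrix(list(1), labels = labels)
    attr(m, "weights") <- structure(1, names = labels)
    attr(m, "ci") <- 0
    attr(m, "distance") <- abs(1 - target[1])
    keep <- if (round(1, tol_dp) == round(target[1], tol_dp)) list(m) else list()
    return(new_jm_search(keep, length(keep), 1L, target, labels, method, tol_dp))
  }

  k <- n * (n - 1) / 2
  vals <- saaty_num / saaty_den
  target_r <- round(target, tol_dp)

  # Chunked enumeration: fix the first max(0, k - 4) cells per chunk so each
  # vectorised block holds at most 17^4 = 83,521 candidates.
  free <- min(k, 4L)
  fixed <- k - free
  fixed_grid <- if (fixed > 0) {
    as.matrix(expand.grid(rep(list(seq_len(17L)), fixed), KEEP.OUT.ATTRS = FALSE))
  } else {
    matrix(integer(), nrow = 1, ncol = 0)
  }
  free_grid <- as.matrix(expand.grid(rep(list(seq_len(17L)), free),
                                     KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first column fastest; column order chosen so the
  # overall enumeration is row-major over the upper triangle.
  n_enum <- 0
  hit_idx <- list()   # integer cell-index rows of matches
  hit_w <- list()

  # Upper-triangle coordinates in row-major order.
  coords <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  coords <- coords[order(coords[, 1], coords[, 2]), , drop = FALSE]

  for (chunk in seq_len(nrow(fixed_grid))) {
    idx <- cbind(matrix(rep(fixed_grid[chunk, ], each = nrow(free_grid)),
                        nrow = nrow(free_grid)),
                 free_grid)
    reps <- nrow(idx)
    cells <- matrix(vals[idx], reps, k)
    w <- weights_batch(cells, n, coords, method)
    ok <- rep(TRUE, reps)
    for (i in seq_len(n)) ok <- ok & (round(w[, i], tol_dp) == target_r[i])
    n_enum <- n_enum + reps
    if (any(ok)) {
      hit_idx[[length(hit_idx) + 1]] <- idx[ok, , drop = FALSE]
      hit_w[[length(hit_w) + 1]] <- w[ok, , drop = FALSE]
    }
  }

  matches <- list()
  if (length(hit_idx)) {
    idx <- do.call(rbind, hit_idx)
    w <- do.call(rbind, hit_w)
    dist <- apply(abs(sweep(w, 2, target)), 1, max)
    ord <- order(dist)
    idx <- idx[ord, , drop = FALSE]
    w <- w[ord, , drop = FALSE]
    dist <- dist[ord]
    n_keep <- min(nrow(idx), max_results)
    for (r in seq_len(n_keep)) {
      num <- matrix(1L, n, n); den <- matrix(1L, n, n)
      for (c in seq_len(k)) {
        i <- coords[c, 1]; j <- coords[c, 2]
        num[i, j] <- saaty_num[idx[r, c]]
        den[i, j] <- saaty_den[idx[r, c]]
        num[j, i] <- saaty_den[idx[r, c]]
        den[j, i] <- saaty_num[idx[r, c]]
      }
      m <- structure(list(labels = labels, num = num, den = den),
                     class = "judgment_matrix")
      ww <- structure(w[r, ], names = labels)
      attr(m, "weights") <- ww
      attr(m, "ci") <- consistency_index(estimate_lambda_max(m, ww), n)
      attr(m, "distance") <- dist[r]
      matches[[r]] <- m
    }
    n_matches <- nrow(idx)
  } else {
    n_matches <- 0L
  }
  new_jm_search(matches, n_matches, n_enum, target, labels, method, tol_dp)
}

new_jm_search <- function(matches, n_matches, n_enum, target, labels, method, tol_dp) {
  structure(list(matches = matches, n_matches = n_matches,
                 n_enumerated = n_enum,
                 target = structure(target, names = labels),
                 method = method, tol_dp = tol_dp),
            class = "jm_search")
}

#' @export
print.jm_search <- function(x, ...) {
  cat(sprintf("Judgment-matrix search: %d match(es) among %s candidates\n",
              x$n_matches, format(x$n_enumerated, big.mark = ",")))
  cat(sprintf("  target (%s, %d dp): %s\n", x$method, x$tol_dp,
              paste(round(x$target, x$tol_dp), collapse = ", ")))
  if (x$n_matches == 0) {
    cat("  certified empty: no Saaty matrix of this order yields these weights\n")
  } else {
    show <- min(length(x$matches), 3L)
    for (r in seq_len(show)) {
      m <- x$matches[[r]]
      cat(sprintf("  match %d (CI %.4f, max-norm distance %.2e):\n",
                  r, attr(m, "ci"), attr(m, "distance")))
      print(m)
    }
    if (length(x$matches) > show) {
      cat(sprintf("  ... and %d more retained match(es)\n", length(x$matches) - show))
    }
  }
  invisible(x)
}

# Vectorised priority weights for a batch of reciprocal matrices described by
# their upper-triangle cells (columns of `cells`, coordinates in `coords`).
weights_batch <- function(cells, n, coords, method) {
  reps <- nrow(cells)
  A <- matrix(vector("list", n * n), n, n)
  for (i in seq_len(n)) A[[i, i]] <- rep(1, reps)
  for (c in seq_len(ncol(cells))) {
    i <- coords[c, 1]; j <- coords[c, 2]
    A[[i, j]] <- cells[, c]
    A[[j, i]] <- 1 / cells[, c]
  }
  if (method == "column_norm") {
    w <- matrix(0, reps, n)
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) s <- s + A[[i, j]]
      for (i in seq_len(n)) w[, i] <- w[, i] + A[[i, j]] / s
    }
    w / n
  } else {
    w <- matrix(1 / n, reps, n)
    for (it in seq_len(500L)) {
      v <- matrix(0, reps, n)
      for (i in seq_len(n)) {
        acc <- 0
        for (j in seq_len(n)) acc <- acc + A[[i, j]] * w[, j]
        v[, i] <- acc
      }
      v <- v / rowSums(v)
      if (max(abs(v - w)) < 1e-12) break
      w <- v
    }
    v
  }
}
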