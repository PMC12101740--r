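# Judgment matrices on the Saaty scale, stored as exact rationals
# (integer numerator/denominator) so that reciprocity a_ji = 1/a_ij holds
# exactly rather than to floating-point tolerance.

# The admissible Saaty comparison values {1/9, ..., 1/2, 1, 2, ..., 9},
# as (numerator, denominator) pairs in ascending order.
saaty_num <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)
saaty_den <- c(9L, 8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)

# Parse one entry: a number, or a fraction string like "1/7".
parse_rational <- function(x) {
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("^[0-9]+\\s*/\\s*[0-9]+$", x)) {
      parts <- as.integer(strsplit(x, "/")[[1]])
      return(c(num = parts[1], den = parts[2]))
    }
    x <- suppressWarnings(as.numeric(x))
  }
  if (!is.numeric(x) || is.na(x)) {
    stop("judgment-matrix entry is neither a number nor a fraction string", call. = FALSE)
  }
  # Small rationals only (Saaty-scale style values); match p/q with q <= 1000.
  for (q in 1:1000) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9 * max(1, abs(p))) {
      return(c(num = as.integer(round(p)), den = as.integer(q)))
    }
  }
  stop(sprintf("cannot represent entry %g as a small rational", x), call. = FALSE)
}

#' Construct a pairwise-comparison judgment matrix
#'
#' Builds a positive reciprocal matrix on the Saaty scale, the elementary
#' object of the analytic hierarchy process. Entries are stored as exact
#' rationals: `"1/7"` and `1/7` both parse to the fraction 1/7, and the
#' reciprocity requirement `entries[j, i] == 1 / entries[i, j]` is checked on
#' the rational representation, not in floating point.
#'
#' @param entries A square numeric matrix, or a list of rows whose cells may be
#'   numbers or fraction strings such as `"1/7"`.
#' @param labels Character vector of item names (criteria or alternatives).
#'   Defaults to `dimnames` of `entries` or `item1, item2, ...`.
#' @param validate Logical; validate on construction (default `TRUE`).
#' @param strict_scale Logical; when validating, additionally require every
#'   off-diagonal entry to belong to the Saaty set \{1/9, ..., 1/2, 1, 2, ..., 9\}.
#'
#' @return An object of class `judgment_matrix`: a list with `labels` and
#'   integer matrices `num`, `den` holding the rational entries.
#'
#' @examples
#' m <- judgment_matrix(list(c(1, 7, 7), c("1/7", 1, "1/2"), c("1/7", 2, 1)),
#'                      labels = c("dose", "interval", "infusion"))
#' as.matrix(m)
#' @export
judgment_matrix <- function(entries, labels = NULL, validate = TRUE,
                            strict_scale = FALSE) {
  if (is.matrix(entries)) {
    rows <- lapply(seq_len(nrow(entries)), function(i) entries[i, ])
    if (is.null(labels) && !is.null(rownames(entries))) labels <- rownames(entries)
  } else if (is.list(entries)) {
    rows <- entries
  } else if (is.numeric(entries) && length(entries) == 1) {
    rows <- list(entries)
  } else {
    stop("`entries` must be a square matrix or a list of rows", call. = FALSE)
  }
  n <- length(rows)
  if (any(vapply(rows, length, 1L) != n)) {
    stop("judgment matrix must be square", call. = FALSE)
  }
  num <- matrix(0L, n, n)
  den <- matrix(1L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- parse_rational(rows[[i]][[j]])
      if (r["num"] <= 0L || r["den"] <= 0L) {
        stop(sprintf("entry (%d,%d) is not positive", i, j), call. = FALSE)
      }
      num[i, j] <- r["num"]
      den[i, j] <- r["den"]
    }
  }
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  stopifnot(length(labels) == n)
  m <- structure(list(labels = as.character(labels), num = num, den = den),
                 class = "judgment_matrix")
  if (validate) {
    viol <- validate_matrix(m, strict_scale = strict_scale)
    if (length(viol)) {
      stop(paste(c("invalid judgment matrix:", viol), collapse = "\n  "),
           call. = FALSE)
    }
  }
  m
}

#' Validate a judgment matrix
#'
#' Checks the structural invariants of a pairwise-comparison matrix: unit
#' diagonal, exact reciprocity `a[j,i] = 1/a[i,j]` (on the rational
#' representation), and optionally strict membership of every off-diagonal
#' entry in the Saaty set.
#'
#' @param m A [judgment_matrix].
#' @param strict_scale Logical; require Saaty-set membership off the diagonal.
#' @return Character vector of violations; empty when the matrix is valid.
#' @examples
#' m <- judgment_matrix(list(c(1, 2), c(3, 1)), validate = FALSE)
#' validate_matrix(m)
#' @export
validate_matrix <- function(m, strict_scale = FALSE) {
  stopifnot(inherits(m, "judgment_matrix"))
  n <- nrow(m$num)
  viol <- character()
  for (i in seq_len(n)) {
    if (!(m$num[i, i] == m$den[i, i])) {
      viol <- c(viol, sprintf("diagonal entry (%d,%d) is not 1", i, i))
    }
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        # a_ij * a_ji == 1  <=>  num_ij*num_ji == den_ij*den_ji
        if (as.double(m$num[i, j]) * m$num[j, i] !=
            as.double(m$den[i, j]) * m$den[j, i]) {
          viol <- c(viol, sprintf("reciprocity violation at (%d,%d)", j, i))
        }
      }
    }
  }
  if (strict_scale && n >= 2) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        ok <- any(m$num[i, j] * saaty_den == m$den[i, j] * saaty_num)
        if (!ok) {
          viol <- c(viol,
                    sprintf("scale violation at (%d,%d): %s not in Saaty set",
                            i, j, format_fraction(m$num[i, j], m$den[i, j])))
        }
      }
    }
  }
  viol
}

format_fraction <- function(num, den) {
  ifelse(den == 1L, as.character(num), paste0(num, "/", den))
}

#' @export
as.matrix.judgment_matrix <- function(x, ...) {
  out <- x$num / x$den
  dimnames(out) <- list(x$labels, x$labels)
  out
}

#' @export
dim.judgment_matrix <- function(x) dim(x$num)

#' @export
print.judgment_matrix <- function(x, ...) {
  n <- nrow(x$num)
  cat(sprintf("Judgment matrix (%d x %d) on the Saaty scale\n", n, n))
  disp <- matrix(format_fraction(x$num, x$den), n, n)
  dimnames(disp) <- list(x$labels, x$labels)
  print(disp, quote = FALSE)
  invisible(x)
}
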