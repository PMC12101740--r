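# Goal / criteria / alternatives hierarchies and hierarchical total ranking.

#' Construct an AHP hierarchy
#'
#' A three-level hierarchy: a goal, a criterion layer, and a scheme
#' (alternative) layer with one judgment matrix over the alternatives per
#' criterion. Criterion weights come either from a criteria judgment matrix
#' or from an explicit weight override — the override exists for the common
#' situation where only the published criterion weights survive (e.g. a
#' corrupted or unavailable criteria matrix).
#'
#' @param goal Character name of the decision goal.
#' @param alternative_matrices Named list of [judgment_matrix] objects, one
#'   per criterion, all sharing identical alternative labels in identical
#'   order. Names are the criterion labels.
#' @param criteria_matrix Optional [judgment_matrix] over the criteria.
#' @param criterion_weights Optional named numeric vector of criterion
#'   weights (used instead of `criteria_matrix`; renormalised to sum 1).
#' @return An object of class `ahp_hierarchy`.
#' @examples
#' B <- judgment_matrix(list(c(1, 7, 7), c("1/7", 1, "1/2"), c("1/7", 2, 1)),
#'                      labels = c("dose", "interval", "infusion"))
#' h <- hierarchy("trough overexposure",
#'                alternative_matrices = list(APTT = B, OI = B, CHF = B, CKD = B),
#'                criterion_weights = c(APTT = 0.0584, OI = 0.1899,
#'                                      CHF = 0.1614, CKD = 0.5902))
#' @export
hierarchy <- function(goal, alternative_matrices, criteria_matrix = NULL,
                      criterion_weights = NULL) {
  stopifnot(is.list(alternative_matrices), length(alternative_matrices) >= 1)
  if (is.null(names(alternative_matrices))) {
    names(alternative_matrices) <- paste0("criterion", seq_along(alternative_matrices))
  }
  lab0 <- alternative_matrices[[1]]$labels
  for (nm in names(alternative_matrices)) {
    m <- alternative_matrices[[nm]]
    if (!inherits(m, "judgment_matrix")) {
      stop(sprintf("alternative matrix '%s' is not a judgment_matrix", nm),
           call. = FALSE)
    }
    if (!identical(m$labels, lab0)) {
      stop(sprintf("alternative labels under criterion '%s' differ from the first criterion",
                   nm), call. = FALSE)
    }
  }
  if (is.null(criteria_matrix) && is.null(criterion_weights)) {
    stop("supply either `criteria_matrix` or `criterion_weights`", call. = FALSE)
  }
  if (!is.null(criterion_weights)) {
    stopifnot(is.numeric(criterion_weights), all(criterion_weights > 0))
    if (is.null(names(criterion_weights))) {
      names(criterion_weights) <- names(alternative_matrices)
    }
    if (!setequal(names(criterion_weights), names(alternative_matrices)) ||
        length(criterion_weights) != length(alternative_matrices)) {
      stop("criterion weight names must match the alternative-matrix names",
           call. = FALSE)
    }
    criterion_weights <- criterion_weights[names(alternative_matrices)]
  }
  if (!is.null(criteria_matrix)) {
    stopifnot(inherits(criteria_matrix, "judgment_matrix"))
    if (!identical(criteria_matrix$labels, names(alternative_matrices))) {
      stop("criteria-matrix labels must match the alternative-matrix names",
           call. = FALSE)
    }
  }
  structure(list(goal = goal,
                 criteria_matrix = criteria_matrix,
                 criterion_weights = criterion_weights,
                 alternative_matrices = alternative_matrices),
            class = "ahp_hierarchy")
}

#' @export
print.ahp_hierarchy <- function(x, ...) {
  cat(sprintf("AHP hierarchy: %s\n", x$goal))
  cat(sprintf("  criteria (%d): %s\n", length(x$alternative_matrices),
              paste(names(x$alternative_matrices), collapse = ", ")))
  cat(sprintf("  alternatives (%d): %s\n",
              length(x$alternative_matrices[[1]]$labels),
              paste(x$alternative_matrices[[1]]$labels, collapse = ", ")))
  cat(sprintf("  criterion weights: %s\n",
              if (is.null(x$criteria_matrix)) "explicit override" else "from criteria matrix"))
  invisible(x)
}

#' Fit an analytic hierarchy process model
#'
#' Performs hierarchical total ranking over an [hierarchy()]: extracts local
#' alternative weights under every criterion, aggregates them with the
#' criterion weights into combination weights, and assembles the level-wide
#' consistency statistics. The combination weight of alternative k is
#' `sum_j w_j * b_jk` (criterion weight times local weight); the combined
#' consistency index is `sum_j w_j CI_j` and the combined consistency ratio
#' is `sum_j w_j CI_j / sum_j w_j RI_j`, accepted when below 0.10.
#'
#' @param h An [hierarchy()].
#' @param method Weight-extraction method, `"column_norm"` (default) or
#'   `"eigen"`; see [priority_column_norm()] and [priority_eigen()].
#' @param ri_mode Random-index source, `"table"` (default) or `"simulated"`.
#' @param seed Seed for simulated RI.
#' @param reps Replicates for simulated RI.
#' @return An object of class `ahp` with components
#'   `combination_weights` (named, sums to 1), `combined_ci`, `combined_cr`,
#'   `acceptable`, `ranking` (labels by descending combination weight, ties
#'   flagged), `criterion_weights`, `criterion_ranking`, `per_criterion`
#'   (one `weights` + `consistency_report` pair per criterion),
#'   `criterion_report` (consistency of the criteria matrix, or `NULL` under
#'   a weight override), `method`, and the call.
#' @examples
#' B <- judgment_matrix(list(c(1, 7, 7), c("1/7", 1, "1/2"), c("1/7", 2, 1)),
#'                      labels = c("dose", "interval", "infusion"))
#' h <- hierarchy("trough overexposure",
#'                alternative_matrices = list(APTT = B, OI = B, CHF = B, CKD = B),
#'                criterion_weights = c(APTT = 0.0584, OI = 0.1899,
#'                                      CHF = 0.1614, CKD = 0.5902))
#' fit <- ahp(h)
#' coef(fit)
#' @export
ahp <- function(h, method = c("column_norm", "eigen"),
                ri_mode = c("table", "simulated"), seed = NULL, reps = 500L) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  method <- match.arg(method)
  ri_mode <- match.arg(ri_mode)

  criterion_report <- NULL
  if (!is.null(h$criterion_weights)) {
    cw <- h$criterion_weights / sum(h$criterion_weights)
  } else {
    ca <- analyze_matrix(h$criteria_matrix, method = method, ri_mode = ri_mode,
                         seed = seed, reps = reps)
    cw <- ca$weights
    criterion_report <- ca$report
  }

  per <- lapply(h$alternative_matrices, analyze_matrix, method = method,
                ri_mode = ri_mode, seed = seed, reps = reps)
  alt_labels <- h$alternative_matrices[[1]]$labels
  local <- vapply(per, function(a) as.numeric(a$weights), numeric(length(alt_labels)))
  # local: alternatives x criteria
  comb <- drop(local %*% cw)
  names(comb) <- alt_labels

  ci_j <- vapply(per, function(a) a$report$ci, 1)
  ri_j <- vapply(per, function(a) a$report$ri, 1)
  combined_ci <- sum(cw * ci_j)
  den <- sum(cw * ri_j)
  if (den > 0) {
    combined_cr <- combined_ci / den
  } else if (combined_ci <= 1e-12) {
    combined_cr <- 0
  } else {
    stop("combined consistency ratio undefined: weighted RI is 0 with CI > 0",
         call. = FALSE)
  }

  structure(list(goal = h$goal,
                 combination_weights = comb,
                 combined_ci = combined_ci,
                 combined_cr = combined_cr,
                 acceptable = combined_cr < 0.10,
                 ranking = rank_items(comb),
                 criterion_weights = cw,
                 criterion_ranking = rank_items(cw),
                 per_criterion = per,
                 criterion_report = criterion_report,
                 method = method,
                 ri_mode = ri_mode,
                 call = match.call()),
            class = "ahp")
}

#' Hierarchical total ranking
#'
#' Alias for [ahp()] named after the procedure it performs.
#' @inheritParams ahp
#' @return See [ahp()].
#' @export
total_ranking <- function(h, method = c("column_norm", "eigen"),
                          ri_mode = c("table", "simulated"),
                          seed = NULL, reps = 500L) {
  ahp(h, method = method, ri_mode = ri_mode, seed = seed, reps = reps)
}

#' @export
print.ahp <- function(x, digits = 4, ...) {
  cat(sprintf("Analytic hierarchy process: %s\n", x$goal))
  cat(sprintf("  method: %s weights, RI %s\n", x$method, x$ri_mode))
  cat("\nCombination weights:\n")
  print(round(x$combination_weights, digits))
  cat(sprintf("\nRanking: %s\n", paste(x$ranking, collapse = " > ")))
  if (isTRUE(attr(x$ranking, "ties"))) cat("  (ties present; input order kept)\n")
  cat(sprintf("Combined CI = %.4f, combined CR = %.4f (%s)\n",
              x$combined_ci, x$combined_cr,
              if (x$acceptable) "acceptable" else "NOT acceptable"))
  invisible(x)
}

#' @export
summary.ahp <- function(object, digits = 4, ...) {
  x <- object
  print(x, digits = digits)
  cat("\nCriterion weights:\n")
  print(round(x$criterion_weights, digits))
  cat(sprintf("Criterion ranking: %s\n", paste(x$criterion_ranking, collapse = " > ")))
  if (!is.null(x$criterion_report)) {
    cat("\nCriteria-matrix consistency:\n")
    print(x$criterion_report)
  }
  cat("\nPer-criterion local weights and consistency:\n")
  for (nm in names(x$per_criterion)) {
    a <- x$per_criterion[[nm]]
    cat(sprintf("  %s: (%s)  CI %.4f  CR %.4f\n", nm,
                paste(round(a$weights, digits), collapse = ", "),
                a$report$ci, a$report$cr))
  }
  invisible(x)
}

#' @export
coef.ahp <- function(object, ...) object$combination_weights

#' @export
plot.ahp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$criterion_weights, las = 2, ylab = "weight",
                    main = "Criterion weights", ...)
  graphics::barplot(x$combination_weights, las = 2, ylab = "weight",
                    main = "Combination weights", ...)
  invisible(x)
}
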