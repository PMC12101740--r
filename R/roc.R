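# Stage 3: ROC curves, trapezoidal AUC, Youden-optimal cutoffs, and
# cutoff-stratified overexposure rates.

#' Construct an ROC curve
#'
#' Thresholds are placed at the midpoints between consecutive distinct score
#' values, plus -Inf and +Inf endpoints. For direction `"greater"` a subject
#' is test-positive when its score exceeds the threshold; `"less"` flips the
#' predictor. `"auto"` picks the orientation whose AUC is at least 0.5 and
#' records the choice. AUC is computed by the trapezoidal rule over
#' (1 - specificity, sensitivity), which equals the Mann-Whitney rank
#' statistic with ties counted 1/2. A Hanley-McNeil standard error and 95%
#' interval for the AUC are attached.
#'
#' @param scores Numeric predictor values (finite).
#' @param labels 0/1 outcome (1 = case/overexposed), or logical.
#' @param direction `"auto"` (default), `"greater"` or `"less"`.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_se`, `auc_ci`, `direction`,
#'   `direction_flipped`, and the scores/labels for downstream cutoff
#'   analysis.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' r <- roc_curve(cohort$aptt, cohort$group)
#' r$auc
#' @export
roc_curve <- function(scores, labels, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present: ROC undefined for single-class labels",
         call. = FALSE)
  }

  build <- function(s) {
    u <- sort(unique(s))
    thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(), Inf)
    sens <- vapply(thr, function(t) mean(s[labels == 1L] > t), 1)
    spec <- vapply(thr, function(t) mean(s[labels == 0L] <= t), 1)
    fpr <- 1 - spec
    ord <- order(fpr, sens)
    auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
    list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc)
  }

  flipped <- FALSE
  cur <- build(scores)
  if (direction == "less" || (direction == "auto" && cur$auc < 0.5)) {
    flipped <- direction != "less"
    cur <- build(-scores)
    cur$thresholds <- -cur$thresholds
    used <- "less"
  } else {
    used <- "greater"
  }

  A <- cur$auc
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
               (n1 * n0))
  structure(list(thresholds = cur$thresholds,
                 sensitivity = cur$sensitivity,
                 specificity = cur$specificity,
                 auc = A,
                 auc_se = se,
                 auc_ci = c(max(0, A - 1.96 * se), min(1, A + 1.96 * se)),
                 direction = used,
                 direction_flipped = flipped,
                 scores = scores,
                 labels = labels,
                 n_cases = n1,
                 n_controls = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases vs %d controls, direction '%s'%s\n",
              x$n_cases, x$n_controls, x$direction,
              if (x$direction_flipped) " (auto-flipped)" else ""))
  cat(sprintf("  AUC = %.4f (Hanley-McNeil 95%% CI %.4f-%.4f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.4f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over all curve
#' thresholds. Ties are broken toward the threshold with higher sensitivity
#' (and recorded). The report includes the overexposure counts above and
#' below the optimal cutoff as strata, ready for [stratified_rates()].
#'
#' @param curve An [roc_curve()].
#' @return An object of class `cutoff_report`: `threshold`, `youden`,
#'   `sensitivity`, `specificity`, `tie` (logical), `direction`, and
#'   `strata` (data frame with n and k overexposed on each side of the
#'   cutoff).
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- max(j)
  cand <- which(j >= best - 1e-12)
  tie <- length(cand) > 1
  if (tie) cand <- cand[order(-curve$sensitivity[cand])]
  k <- cand[1]
  thr <- curve$thresholds[k]

  s <- curve$scores; lab <- curve$labels
  pos_side <- if (curve$direction == "greater") s > thr else s < thr
  strata <- data.frame(
    stratum = c(sprintf("%s %.6g", if (curve$direction == "greater") ">" else "<", thr),
                sprintf("%s %.6g", if (curve$direction == "greater") "<=" else ">=", thr)),
    n = c(sum(pos_side), sum(!pos_side)),
    k = c(sum(lab[pos_side]), sum(lab[!pos_side])),
    digits = 2L,
    stringsAsFactors = FALSE)

  structure(list(threshold = thr,
                 youden = best,
                 sensitivity = curve$sensitivity[k],
                 specificity = curve$specificity[k],
                 tie = tie,
                 direction = curve$direction,
                 auc = curve$auc,
                 strata = strata),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff (direction '%s'): %.6g\n",
              x$direction, x$threshold))
  cat(sprintf("  J = %.4f (sensitivity %.4f, specificity %.4f)%s\n",
              x$youden, x$sensitivity, x$specificity,
              if (x$tie) "  [tie broken toward higher sensitivity]" else ""))
  print(stratified_rates(x$strata))
  invisible(x)
}

#' Cutoff-stratified overexposure rates
#'
#' Converts stratum counts (k overexposed of n) to percentage rates. The
#' default `mode = "display"` truncates toward zero at each stratum's
#' `digits` (2 by default, 0 when a rate was printed as an integer) — the
#' convention under which all six published stratum rates (95.12, 95.23, 83,
#' 60.97, 81.67, 50.79) are reproduced exactly; `mode = "round"` applies
#' half-to-even rounding instead.
#'
#' @param counts Data frame with columns `stratum`, `n`, `k` and optionally
#'   `digits` (per-stratum display precision, default 2).
#' @param mode `"display"` (truncate, default) or `"round"` (half-to-even).
#' @return The input with a `rate` column (percent) appended; class
#'   `rate_table`.
#' @examples
#' stratified_rates(data.frame(stratum = "CKD", n = 41, k = 39))
#' @export
stratified_rates <- function(counts, mode = c("display", "round")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(counts), all(c("stratum", "n", "k") %in% names(counts)))
  if (any(counts$n == 0)) stop("stratum with n = 0: rate undefined", call. = FALSE)
  if (any(counts$k < 0 | counts$k > counts$n)) {
    stop("need 0 <= k <= n in every stratum", call. = FALSE)
  }
  digits <- if ("digits" %in% names(counts)) counts$digits else rep(2L, nrow(counts))
  raw <- 100 * counts$k / counts$n
  rate <- if (mode == "display") {
    mapply(trunc_digits, raw, digits)
  } else {
    mapply(round, raw, digits)
  }
  out <- counts
  out$rate <- rate
  class(out) <- c("rate_table", "data.frame")
  out
}
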