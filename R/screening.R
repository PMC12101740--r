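# Stage 1: per-variable two-group comparisons with a significance gate.

new_univariate_result <- function(variable, test, statistic, p, summaries, alpha) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 p = p, summaries = summaries, alpha = alpha,
                 selected = p < alpha),
            class = "univariate_result")
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g%s\n",
              x$variable, x$test, x$statistic, x$p,
              if (x$selected) sprintf("  [selected, p < %g]", x$alpha) else ""))
  invisible(x)
}

#' Compare a continuous variable between two groups
#'
#' Welch two-sample t test (`mode = "t"`), Wilcoxon rank-sum / Mann-Whitney U
#' (`mode = "ranksum"`; exact for small tie-free samples, otherwise normal
#' approximation with mid-rank tie correction), or `mode = "auto"` which
#' uses t for approximately symmetric variables and rank-sum for skewed ones
#' (driven by the variable's declared kind when called through
#' [screen_cohort()]).
#'
#' @param x,y Numeric observations in groups A and B (each `>= 2` values).
#' @param mode `"auto"`, `"t"` or `"ranksum"`.
#' @param variable Variable name for reporting.
#' @param alpha Significance gate (default 0.05).
#' @param pooled Logical: pooled-variance t instead of Welch (default FALSE).
#' @param skewed For `mode = "auto"`: treat as skewed (rank-sum)?
#' @return A `univariate_result` with the test used, statistic, two-sided p,
#'   group summaries and the `selected` flag (`p < alpha`).
#' @export
compare_continuous <- function(x, y, mode = c("auto", "t", "ranksum"),
                               variable = "x", alpha = 0.05,
                               pooled = FALSE, skewed = FALSE) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (mode == "auto") mode <- if (skewed) "ranksum" else "t"
  if (mode == "t") {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        return(new_univariate_result(variable, "t (degenerate)", 0, 1,
                                     summarize_groups(x, y, FALSE), alpha))
      }
      stop("zero variance in both groups: t statistic undefined", call. = FALSE)
    }
    tt <- stats::t.test(x, y, var.equal = pooled)
    new_univariate_result(variable,
                          if (pooled) "t (pooled)" else "t (Welch)",
                          unname(tt$statistic), tt$p.value,
                          summarize_groups(x, y, FALSE), alpha)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    new_univariate_result(variable, "Wilcoxon rank-sum",
                          unname(wt$statistic), wt$p.value,
                          summarize_groups(x, y, TRUE), alpha)
  }
}

summarize_groups <- function(x, y, skewed) {
  if (skewed) {
    list(A = c(median = stats::median(x), q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75))),
         B = c(median = stats::median(y), q1 = unname(stats::quantile(y, 0.25)),
               q3 = unname(stats::quantile(y, 0.75))))
  } else {
    list(A = c(mean = mean(x), sd = stats::sd(x)),
         B = c(mean = mean(y), sd = stats::sd(y)))
  }
}

#' Compare a binary variable between two groups
#'
#' 2x2 contingency analysis of a binary characteristic across the two
#' exposure groups. Continuity-corrected chi-square by default, switching to
#' Fisher's exact test when any expected cell count falls below 5 (the rule
#' applied is reported). `test` overrides the rule.
#'
#' @param a,b,c,d Non-negative integer cell counts: rows are groups, columns
#'   presence/absence, i.e. the table is `rbind(c(a, b), c(c, d))`.
#' @param variable Variable name for reporting.
#' @param alpha Significance gate (default 0.05).
#' @param test `"auto"` (expected-count rule), `"chisq"` or `"fisher"`.
#' @return A `univariate_result`; `test` records which test the rule chose.
#' @examples
#' compare_binary(3, 54, 38, 99)  # comorbidity enriched in the second group
#' @export
compare_binary <- function(a, b, c, d, variable = "x", alpha = 0.05,
                           test = c("auto", "chisq", "fisher")) {
  test <- match.arg(test)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  tab <- matrix(as.numeric(counts), 2, 2, byrow = TRUE)
  if (sum(tab) < 1) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a table margin is zero: association test undefined", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (test == "auto") test <- if (any(expected < 5)) "fisher" else "chisq"
  if (test == "fisher") {
    ft <- stats::fisher.test(tab)
    new_univariate_result(variable, "Fisher exact", unname(ft$estimate),
                          ft$p.value, list(table = tab, expected = expected),
                          alpha)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    new_univariate_result(variable, "chi-square (Yates)",
                          unname(ct$statistic), ct$p.value,
                          list(table = tab, expected = expected), alpha)
  }
}

#' Screen cohort variables against the exposure label
#'
#' Stage-1 univariate screening: every variable is compared between the
#' compliant (`group == 0`) and overexposed (`group == 1`) groups and gated
#' at `p < alpha`. Test choice per variable: Welch t for variables declared
#' `"normal"`, Wilcoxon rank-sum for `"lognormal"` (skewed) variables,
#' chi-square/Fisher for `"binary"` — the inferred mapping from how each
#' variable kind is summarised, configurable through the specs.
#'
#' @param cohort Data frame with a 0/1 `group` column (see
#'   [generate_cohort()]).
#' @param specs List of [variable_spec()] objects describing the variables to
#'   screen; defaults to the spec attached to the cohort.
#' @param alpha Significance gate in (0, 1); default 0.05.
#' @return A data frame of class `screening_result`: one row per variable
#'   with `variable`, `test`, `statistic`, `p`, `selected`, in spec order.
#'   The full `univariate_result` objects are attached as attribute
#'   `"results"`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' screen_cohort(cohort)
#' @export
screen_cohort <- function(cohort, specs = NULL, alpha = 0.05) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]", call. = FALSE)
  if (is.null(specs)) {
    sp <- attr(cohort, "spec")
    if (is.null(sp)) {
      stop("no variable specs supplied and none attached to the cohort",
           call. = FALSE)
    }
    specs <- sp$variables
  }
  stopifnot("group" %in% names(cohort))
  g <- cohort$group
  results <- lapply(specs, function(v) {
    if (!v$name %in% names(cohort)) {
      stop(sprintf("variable '%s' not present in the cohort", v$name), call. = FALSE)
    }
    vals <- cohort[[v$name]]
    switch(v$kind,
           normal = compare_continuous(vals[g == 0], vals[g == 1], mode = "t",
                                       variable = v$name, alpha = alpha),
           lognormal = compare_continuous(vals[g == 0], vals[g == 1],
                                          mode = "ranksum", variable = v$name,
                                          alpha = alpha),
           binary = compare_binary(sum(vals[g == 0] == 1), sum(vals[g == 0] == 0),
                                   sum(vals[g == 1] == 1), sum(vals[g == 1] == 0),
                                   variable = v$name, alpha = alpha),
           stop(sprintf("unknown variable kind '%s' for '%s'", v$kind, v$name),
                call. = FALSE))
  })
  out <- data.frame(
    variable = vapply(results, `[[`, "", "variable"),
    test = vapply(results, `[[`, "", "test"),
    statistic = vapply(results, `[[`, 1, "statistic"),
    p = vapply(results, `[[`, 1, "p"),
    selected = vapply(results, `[[`, TRUE, "selected"),
    stringsAsFactors = FALSE)
  attr(out, "results") <- results
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Write screening results as CSV or JSON
#'
#' @param x A `screening_result`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_screening <- function(x, path) {
  df <- as.data.frame(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
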