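# Synthetic two-group cohort generation.
#
# Emulates a case-control-style table of ICU patients: continuous labs
# summarised per exposure group as mean +/- SD (modelled normal, truncated at
# the physiologic floor 0) or median [IQR] (modelled log-normal, matched by
# quartiles), and binary comorbidities as per-group prevalences. Exposure
# label: 0 = trough concentration within the compliant 10-20 ug/mL window,
# 1 = overexposed (> 20 ug/mL).

#' Specify one cohort variable
#'
#' @param name Variable (column) name.
#' @param kind `"normal"` (summarised mean, sd), `"lognormal"` (summarised
#'   median, q1, q3) or `"binary"` (summarised prevalence).
#' @param compliant,overexposed Per-group parameter lists: `list(mean=, sd=)`
#'   for normal, `list(median=, q1=, q3=)` for log-normal, `list(prev=)` for
#'   binary. Used in fixed-margins generation.
#' @param pooled Optional single parameter list of the same shape, used in
#'   mechanism-mode generation (covariates drawn from one pooled
#'   distribution, labels from a logistic model).
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind = c("normal", "lognormal", "binary"),
                          compliant = NULL, overexposed = NULL, pooled = NULL) {
  kind <- match.arg(kind)
  check <- function(p, where) {
    if (is.null(p)) return(invisible())
    if (kind == "normal") {
      stopifnot(!is.null(p$mean), !is.null(p$sd))
      if (p$sd <= 0) stop(sprintf("%s: sd must be > 0 for '%s'", where, name), call. = FALSE)
    } else if (kind == "lognormal") {
      stopifnot(!is.null(p$median), !is.null(p$q1), !is.null(p$q3))
      if (!(p$q1 <= p$median && p$median <= p$q3)) {
        stop(sprintf("%s: need q1 <= median <= q3 for '%s'", where, name), call. = FALSE)
      }
      if (p$q1 <= 0) stop(sprintf("%s: quartiles must be positive for '%s'", where, name), call. = FALSE)
    } else {
      stopifnot(!is.null(p$prev))
      if (p$prev < 0 || p$prev > 1) {
        stop(sprintf("%s: prevalence must lie in [0,1] for '%s'", where, name), call. = FALSE)
      }
    }
  }
  check(compliant, "compliant"); check(overexposed, "overexposed"); check(pooled, "pooled")
  structure(list(name = name, kind = kind, compliant = compliant,
                 overexposed = overexposed, pooled = pooled),
            class = "variable_spec")
}

#' Specify a synthetic cohort
#'
#' Two mutually exclusive generation modes:
#' * **fixed margins** (default): exactly `n_compliant` and `n_overexposed`
#'   rows, each variable drawn from its per-group parameters — reproduces a
#'   published two-group summary table.
#' * **mechanism**: covariates drawn from each variable's `pooled`
#'   parameters and the exposure label drawn from a logistic model
#'   `logit P(overexposed) = intercept + sum(coef * covariate)`.
#'
#' @param variables List of [variable_spec()] objects.
#' @param n_compliant,n_overexposed Group sizes (fixed-margins mode); in
#'   mechanism mode their sum is the total cohort size.
#' @param mechanism Optional `list(intercept =, coef = c(name = value, ...))`
#'   enabling mechanism mode.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(variables, n_compliant, n_overexposed, mechanism = NULL) {
  stopifnot(is.list(variables), length(variables) >= 1)
  stopifnot(all(vapply(variables, inherits, TRUE, "variable_spec")))
  if (n_compliant <= 0 || n_overexposed <= 0) {
    stop("group sizes must be positive", call. = FALSE)
  }
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate variable names", call. = FALSE)
  names(variables) <- nms
  if (!is.null(mechanism)) {
    stopifnot(is.list(mechanism), !is.null(mechanism$intercept), !is.null(mechanism$coef))
    unknown <- setdiff(names(mechanism$coef), nms)
    if (length(unknown)) {
      stop(sprintf("mechanism coefficients refer to unknown variable(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (v in variables) {
      if (is.null(v$pooled)) {
        stop(sprintf("mechanism mode requires pooled parameters for '%s'", v$name),
             call. = FALSE)
      }
    }
  } else {
    for (v in variables) {
      if (is.null(v$compliant) || is.null(v$overexposed)) {
        stop(sprintf("fixed-margins mode requires per-group parameters for '%s'", v$name),
             call. = FALSE)
      }
    }
  }
  structure(list(variables = variables,
                 n_compliant = as.integer(n_compliant),
                 n_overexposed = as.integer(n_overexposed),
                 mechanism = mechanism),
            class = "cohort_spec")
}

#' Log-normal parameters from a median and quartiles
#'
#' Matches a log-normal distribution to a published `median [q1, q3]`
#' summary: log-scale location `ln(median)` and log-scale spread
#' `(ln q3 - ln q1) / (2 z_{0.75})` where `z_{0.75} = qnorm(0.75)`. The
#' returned distribution reproduces the median and the interquartile ratio
#' `q3/q1` exactly; both individual quartiles are reproduced exactly when
#' the summary is symmetric on the log scale (`median^2 = q1 * q3`), the
#' closest a two-parameter log-normal can come to an asymmetric summary.
#'
#' @param median,q1,q3 Positive reals with `q1 <= median <= q3`.
#' @return List with `meanlog` and `sdlog`.
#' @examples
#' p <- lognormal_from_quartiles(36.35, 32.15, 42.20)
#' qlnorm(c(0.25, 0.5, 0.75), p$meanlog, p$sdlog)
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0)) {
    stop("median and quartiles must be positive", call. = FALSE)
  }
  if (!(q1 <= median && median <= q3)) {
    stop("need q1 <= median <= q3", call. = FALSE)
  }
  list(meanlog = log(median), sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

# Draw n values for one variable from one parameter set. Continuous values
# are kept strictly above the physiologic floor 0 by rejection.
draw_variable <- function(v, params, n) {
  switch(v$kind,
         normal = {
           x <- stats::rnorm(n, params$mean, params$sd)
           while (any(bad <- x <= 0)) {
             x[bad] <- stats::rnorm(sum(bad), params$mean, params$sd)
           }
           x
         },
         lognormal = {
           p <- lognormal_from_quartiles(params$median, params$q1, params$q3)
           stats::rlnorm(n, p$meanlog, p$sdlog)
         },
         binary = stats::rbinom(n, 1L, params$prev))
}

#' Generate a synthetic cohort
#'
#' Draws a per-patient table from a [cohort_spec()]; deterministic for a
#' fixed seed. Column `group` codes exposure (0 = compliant, 1 =
#' overexposed), matching the compliant 10-20 ug/mL vs > 20 ug/mL trough
#' classification.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return A `data.frame` with columns `id`, one column per variable, and
#'   `group`; the spec is attached as attribute `"spec"`.
#' @examples
#' spec <- default_cohort_spec()
#' cohort <- generate_cohort(spec, seed = 1)
#' table(cohort$group)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    if (is.null(spec$mechanism)) {
      n0 <- spec$n_compliant; n1 <- spec$n_overexposed
      cols <- lapply(spec$variables, function(v) {
        c(draw_variable(v, v$compliant, n0), draw_variable(v, v$overexposed, n1))
      })
      group <- rep(c(0L, 1L), c(n0, n1))
    } else {
      n <- spec$n_compliant + spec$n_overexposed
      cols <- lapply(spec$variables, function(v) draw_variable(v, v$pooled, n))
      eta <- rep(spec$mechanism$intercept, n)
      for (nm in names(spec$mechanism$coef)) {
        eta <- eta + spec$mechanism$coef[[nm]] * cols[[nm]]
      }
      group <- stats::rbinom(n, 1L, stats::plogis(eta))
    }
    out <- data.frame(id = seq_along(group), cols,
                      group = group, check.names = FALSE)
    attr(out, "spec") <- spec
    out
  })
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with a header row, one patient per row; the exposure column
#' `group` is coded 0 = compliant, 1 = overexposed.
#'
#' @param cohort Data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort` returns the data frame; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  if (!"group" %in% names(out)) {
    stop("cohort CSV must contain a 'group' column (0 = compliant, 1 = overexposed)",
         call. = FALSE)
  }
  if (!all(out$group %in% c(0L, 1L))) {
    stop("'group' must be coded 0/1", call. = FALSE)
  }
  out
}

#' Write / read a cohort specification as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `read_cohort_spec` returns the `cohort_spec`; `write_cohort_spec`
#'   returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- list(n_compliant = spec$n_compliant,
            n_overexposed = spec$n_overexposed,
            mechanism = spec$mechanism,
            variables = lapply(unname(spec$variables), function(v) {
              Filter(Negate(is.null),
                     list(name = v$name, kind = v$kind, compliant = v$compliant,
                          overexposed = v$overexposed, pooled = v$pooled))
            }))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  vars <- lapply(x$variables, function(v) {
    variable_spec(v$name, v$kind, compliant = v$compliant,
                  overexposed = v$overexposed, pooled = v$pooled)
  })
  mech <- x$mechanism
  if (!is.null(mech)) mech$coef <- unlist(mech$coef)
  cohort_spec(vars, x$n_compliant, x$n_overexposed, mechanism = mech)
}
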