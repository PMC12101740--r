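# End-to-end orchestration: cohort -> screening -> logistic fit -> ROC /
# cutoffs -> AHP ranking, with explicit seeds and provenance.

#' Configure a pipeline run
#'
#' @param input Data source: `"fixtures"` (reference inputs only — AHP and
#'   stratified rates, no patient-level stages), `"synthetic"` (generate a
#'   cohort from `spec`) or `"csv"` (read a cohort from `path`).
#' @param spec A [cohort_spec()] for synthetic input (default
#'   [default_cohort_spec()]).
#' @param path Cohort CSV path for `input = "csv"`.
#' @param specs Variable specs for screening a CSV cohort (synthetic cohorts
#'   carry their own).
#' @param alpha Univariate screening gate (default 0.05).
#' @param logistic_terms Character vector of covariates for the logistic
#'   stage, or `NULL` (default) to use the screening-selected set.
#' @param roc_variables Covariates to run ROC analysis on, besides the
#'   fitted risk score (default `c("aptt", "oi")`).
#' @param hierarchy An [hierarchy()] for the AHP stage (default: the
#'   reference hierarchy with the published criterion-weight override, since
#'   the criterion judgment matrix is unrecoverable).
#' @param method,ri_mode AHP options, see [ahp()].
#' @param seed Integer seed controlling every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "fixtures", "csv"),
                            spec = default_cohort_spec(),
                            path = NULL, specs = NULL,
                            alpha = 0.05,
                            logistic_terms = NULL,
                            roc_variables = c("aptt", "oi"),
                            hierarchy = reference_fixtures()$hierarchy,
                            method = "column_norm",
                            ri_mode = "table",
                            seed = 1L) {
  input <- match.arg(input)
  if (input == "csv" && is.null(path)) {
    stop("input = \"csv\" needs `path`", call. = FALSE)
  }
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(input = input, spec = spec, path = path, specs = specs,
                 alpha = alpha, logistic_terms = logistic_terms,
                 roc_variables = roc_variables, hierarchy = hierarchy,
                 method = method, ri_mode = ri_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — cohort acquisition, univariate screening,
#' multivariable logistic regression on the screening-selected set, ROC /
#' Youden cutoff analysis (on the fitted risk score and each configured
#' covariate), and AHP hierarchical total ranking — and returns all stage
#' outputs with provenance (config hash, seed, package version). Any stage
#' failure aborts with the stage name; completed stage outputs are retained
#' in the error condition where possible.
#'
#' With `input = "fixtures"` the patient-level stages are skipped (recorded
#' as explicit notices) and the AHP and stratified-rate stages run from the
#' bundled reference inputs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report` with elements `cohort`,
#'   `screening`, `logistic`, `roc` (named list of `roc_curve` +
#'   `cutoff_report` pairs), `ahp`, `rates`, `notices`, `provenance`.
#' @examples
#' rep <- run_pipeline(pipeline_config(input = "fixtures"))
#' rep$ahp$ranking
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notices <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- screening <- logistic <- NULL
  roc <- list()

  if (config$input != "fixtures") {
    cohort <- stage("cohort", switch(config$input,
      synthetic = generate_cohort(config$spec, seed = config$seed),
      csv = read_cohort(config$path)))
    specs <- config$specs %||% attr(cohort, "spec")$variables
    screening <- stage("screening",
                       screen_cohort(cohort, specs = specs, alpha = config$alpha))
    terms <- config$logistic_terms %||% screening$variable[screening$selected]
    if (length(terms) == 0) {
      notices <- c(notices, "logistic stage skipped: no variable passed the screening gate")
    } else {
      fml <- stats::reformulate(terms, response = "group")
      logistic <- stage("logistic", fit_logistic(fml, cohort))
    }
    roc_vars <- intersect(config$roc_variables, names(cohort))
    roc <- stage("roc", {
      out <- list()
      if (!is.null(logistic)) {
        risk <- predict_risk(logistic, cohort)
        rc <- roc_curve(risk, cohort$group)
        out$risk_score <- list(curve = rc, cutoff = youden_optimal(rc))
      }
      for (v in roc_vars) {
        rc <- roc_curve(cohort[[v]], cohort$group)
        out[[v]] <- list(curve = rc, cutoff = youden_optimal(rc))
      }
      out
    })
    rates <- NULL
  } else {
    notices <- c(notices,
                 "patient-level stages (screening, logistic, ROC) not run: fixture input has no cohort")
    rates <- stage("rates", stratified_rates(reference_fixtures()$strata))
  }

  ahp_fit <- stage("ahp", ahp(config$hierarchy, method = config$method,
                              ri_mode = config$ri_mode, seed = config$seed))

  structure(list(cohort = cohort,
                 screening = screening,
                 logistic = logistic,
                 roc = roc,
                 ahp = ahp_fit,
                 rates = rates,
                 notices = notices,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   package_version = as.character(utils::packageVersion("vancahp")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  config %s, seed %d, vancahp %s\n",
              x$provenance$config_hash, x$provenance$seed,
              x$provenance$package_version))
  for (n in x$notices) cat(sprintf("  note: %s\n", n))
  if (!is.null(x$screening)) {
    cat(sprintf("  screening: %d/%d variables selected\n",
                sum(x$screening$selected), nrow(x$screening)))
  }
  if (!is.null(x$logistic)) {
    cat(sprintf("  logistic: %d terms, converged = %s\n",
                length(x$logistic$coefficients) - 1, x$logistic$converged))
  }
  if (length(x$roc)) {
    cat(sprintf("  ROC: %s\n",
                paste(sprintf("%s AUC %.4f", names(x$roc),
                              vapply(x$roc, function(r) r$curve$auc, 1)),
                      collapse = ", ")))
  }
  cat(sprintf("  AHP ranking: %s\n", paste(x$ahp$ranking, collapse = " > ")))
  invisible(x)
}

#' Render a run report
#'
#' @param r A [run_pipeline()] report.
#' @param format `"text"` or `"json"`. AHP quantities are reported at 4
#'   decimal places, rates at 2.
#' @param path Optional file to write to.
#' @return Character vector of lines (text) or the report list (json),
#'   invisibly when `path` is given.
#' @export
make_report <- function(r, format = c("text", "json"), path = NULL) {
  stopifnot(inherits(r, "run_report"))
  format <- match.arg(format)
  if (format == "json") {
    out <- list(
      provenance = r$provenance,
      notices = if (length(r$notices)) r$notices else "none",
      screening = if (is.null(r$screening)) "not run" else as.data.frame(r$screening),
      logistic = if (is.null(r$logistic)) "not run" else {
        list(variables = r$logistic$x_names,
             or = round(r$logistic$or, 4),
             ci_lower = round(r$logistic$ci_lower, 4),
             ci_upper = round(r$logistic$ci_upper, 4),
             p = round(r$logistic$p, 4),
             converged = r$logistic$converged,
             separated = r$logistic$separated)
      },
      roc = if (!length(r$roc)) "not run" else {
        lapply(r$roc, function(x) {
          list(auc = round(x$curve$auc, 4),
               auc_ci = round(x$curve$auc_ci, 4),
               direction = x$curve$direction,
               cutoff = x$cutoff$threshold,
               youden = round(x$cutoff$youden, 4),
               sensitivity = round(x$cutoff$sensitivity, 4),
               specificity = round(x$cutoff$specificity, 4))
        })
      },
      rates = if (is.null(r$rates)) "not run" else as.data.frame(r$rates),
      ahp = list(combination_weights = as.list(round(r$ahp$combination_weights, 4)),
                 ranking = as.character(r$ahp$ranking),
                 combined_ci = round(r$ahp$combined_ci, 4),
                 combined_cr = round(r$ahp$combined_cr, 4),
                 acceptable = r$ahp$acceptable,
                 criterion_weights = as.list(round(r$ahp$criterion_weights, 4)),
                 criterion_ranking = as.character(r$ahp$criterion_ranking)))
    if (!is.null(path)) {
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
      return(invisible(out))
    }
    return(out)
  }
  lines <- c("== Pipeline report ==",
             sprintf("config %s | seed %d | vancahp %s",
                     r$provenance$config_hash, r$provenance$seed,
                     r$provenance$package_version),
             vapply(r$notices, function(n) paste("note:", n), ""))
  lines <- c(lines, "", "-- Screening --")
  lines <- c(lines, if (is.null(r$screening)) "not run" else
    utils::capture.output(print.data.frame(
      transform(as.data.frame(r$screening),
                statistic = round(statistic, 4), p = round(p, 4)))))
  lines <- c(lines, "", "-- Logistic regression --")
  lines <- c(lines, if (is.null(r$logistic)) "not run" else
    utils::capture.output(print(summary(r$logistic))))
  lines <- c(lines, "", "-- ROC / cutoffs --")
  if (!length(r$roc)) {
    lines <- c(lines, "not run")
  } else {
    for (nm in names(r$roc)) {
      lines <- c(lines, sprintf("[%s]", nm),
                 utils::capture.output({print(r$roc[[nm]]$curve); print(r$roc[[nm]]$cutoff)}))
    }
  }
  if (!is.null(r$rates)) {
    lines <- c(lines, "", "-- Stratified overexposure rates --",
               utils::capture.output(print.data.frame(as.data.frame(r$rates))))
  }
  lines <- c(lines, "", "-- AHP --", utils::capture.output(summary(r$ahp)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
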