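# Stage 2: multivariable binary logistic regression, fitted by iteratively
# reweighted least squares (Fisher scoring on the binomial log-likelihood),
# reporting odds ratios with Wald 95% intervals.

#' Fit a binary logistic regression
#'
#' Maximises the binomial log-likelihood by iteratively reweighted least
#' squares; convergence is declared when the log-likelihood changes by less
#' than `tol` between iterations. Standard errors come from the inverse
#' observed information at the optimum; odds ratios are `exp(coef)` with
#' Wald 95% intervals `exp(coef +/- 1.96 SE)` and two-sided Wald p-values.
#'
#' Complete or quasi-complete separation is reported via the `separated`
#' flag (diverging coefficients with fitted probabilities pinned at 0/1),
#' never as a silent estimate. Rank-deficient designs raise an error naming
#' the aliased columns.
#'
#' @param formula,data Model formula and data frame (e.g.
#'   `group ~ aptt + oi + chf + ckd`), or alternatively
#' @param x,y Design matrix (without intercept column; one is added) and 0/1
#'   response, bypassing the formula interface.
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @return An object of class `logit_fit`: coefficients, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p`, `vcov`, fitted probabilities, linear
#'   predictors, log-likelihood, `iterations`, `converged`, `separated`,
#'   `gradient_norm`, and the model terms for prediction.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' fit <- fit_logistic(group ~ aptt + oi + chf + ckd, cohort)
#' summary(fit)
#' @export
fit_logistic <- function(formula = NULL, data = NULL, x = NULL, y = NULL,
                         tol = 1e-8, max_iter = 50L) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    terms_obj <- attr(mf, "terms")
    X <- stats::model.matrix(terms_obj, mf)
    y <- stats::model.response(mf)
  } else {
    stopifnot(!is.null(x), !is.null(y))
    X <- cbind(`(Intercept)` = 1, as.matrix(x))
    terms_obj <- NULL
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class: logistic likelihood unbounded", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }

  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    fit_wls <- stats::lm.wfit(X, z, w)
    beta <- fit_wls$coefficients
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  it_used <- it
  grad <- drop(crossprod(X, y - mu))
  info <- crossprod(X * (mu * (1 - mu)), X)
  vc <- tryCatch(solve(info), error = function(e) {
    stop("observed information is singular at the optimum", call. = FALSE)
  })
  se <- sqrt(diag(vc))
  separated <- any(pmin(mu, 1 - mu) < 1e-8) || max(abs(beta)) > 15

  zstat <- beta / se
  structure(list(coefficients = beta,
                 se = se,
                 or = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(zstat)),
                 vcov = vc,
                 fitted = mu,
                 linear_predictors = eta,
                 logLik = ll,
                 iterations = it_used,
                 converged = converged,
                 separated = separated,
                 gradient_norm = max(abs(grad)),
                 terms = terms_obj,
                 xlevels = if (!is.null(terms_obj)) stats::.getXlevels(terms_obj, mf) else NULL,
                 x_names = colnames(X),
                 y = y,
                 n = length(y)),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (IRLS), n = %d, %d iterations%s\n",
              x$n, x$iterations,
              if (x$converged) "" else "  [NOT converged]"))
  if (x$separated) {
    cat("  WARNING: separation detected; estimates and intervals are unreliable\n")
  }
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
summary.logit_fit <- function(object, ...) {
  x <- object
  tab <- data.frame(OR = x$or,
                    `CI lower` = x$ci_lower,
                    `CI upper` = x$ci_upper,
                    `P-value` = x$p,
                    check.names = FALSE,
                    row.names = x$x_names)
  out <- list(fit = x, table = tab)
  class(out) <- "summary.logit_fit"
  out
}

#' @export
print.summary.logit_fit <- function(x, ...) {
  print(x$fit)
  cat("\nOdds ratios with Wald 95% intervals:\n")
  print(round(x$table, 4))
  cat(sprintf("\nlogLik = %.4f, max |score| = %.2e\n",
              x$fit$logLik, x$fit$gradient_norm))
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients), class = "logLik")
}

#' @export
residuals.logit_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  }
  r
}

#' Predict overexposure risk
#'
#' Inverse-logit of the linear predictor for new observations; probabilities
#' lie strictly in (0, 1).
#'
#' @param fit A converged [fit_logistic()] object.
#' @param newdata Data frame with the model's covariates (formula interface)
#'   or a numeric matrix matching the design columns.
#' @return Numeric vector of predicted probabilities.
#' @export
predict_risk <- function(fit, newdata) {
  stopifnot(inherits(fit, "logit_fit"))
  if (!fit$converged) {
    stop("model did not converge; refusing to predict", call. = FALSE)
  }
  if (!is.null(fit$terms)) {
    tt <- stats::delete.response(fit$terms)
    missing_vars <- setdiff(all.vars(tt), names(newdata))
    if (length(missing_vars)) {
      stop(sprintf("newdata lacks covariate(s): %s",
                   paste(missing_vars, collapse = ", ")), call. = FALSE)
    }
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    xlev = fit$xlevels))
  } else {
    X <- cbind(1, as.matrix(newdata))
    if (ncol(X) != length(fit$coefficients)) {
      stop("newdata columns do not match the fitted design", call. = FALSE)
    }
  }
  drop(stats::plogis(X %*% fit$coefficients))
}

#' @export
predict.logit_fit <- function(object, newdata,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  pr <- predict_risk(object, newdata)
  if (type == "response") pr else stats::qlogis(pr)
}

#' Write a logistic fit summary as CSV or JSON
#'
#' Mirrors the conventional reporting table: Variables, OR, 95% CI bounds,
#' P-value.
#'
#' @param fit A `logit_fit`.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_logistic <- function(fit, path) {
  tab <- data.frame(variable = fit$x_names,
                    or = fit$or, ci_lower = fit$ci_lower,
                    ci_upper = fit$ci_upper, p = fit$p,
                    stringsAsFactors = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
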