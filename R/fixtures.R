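# Bundled reference inputs: the published summary values of the motivating
# clinical analysis (a cohort of 194 mechanically ventilated ICU patients on
# vancomycin, 57 with compliant troughs and 137 overexposed), shipped as
# exact fixtures so every downstream stage can run without patient-level
# records.

#' Reference analysis fixtures
#'
#' Returns the bundled reference inputs for the vancomycin trough
#' overexposure analysis:
#'
#' * `scheme_matrix` — the 3x3 scheme-layer judgment matrix comparing three
#'   dosing-regimen alternatives (increasing dose, increasing the dosing
#'   interval, delaying infusion time); identical under all four criteria.
#' * `criterion_weights` — published weights of the four risk-factor
#'   criteria (APTT, OI, CHF, moderate/severe CKD) as printed; they sum to
#'   0.9999 and are renormalised wherever they enter a hierarchy.
#' * `criterion_consistency` — the published criterion-layer CI (0.0796) and
#'   CR (0.0885). The criterion-layer judgment matrix itself is
#'   typographically corrupted in the publication, so these figures are
#'   carried as fixture values, not recomputed;
#'   [search_matrix_for_weights()] exists to explore candidate matrices.
#' * `strata` — cutoff-stratified overexposure counts (k overexposed of n):
#'   moderate/severe CKD 39/41, CHF 20/21, OI < 245 93/112, OI >= 245 50/82,
#'   APTT > 33.65 s 107/131, APTT <= 33.65 s 32/63. `digits` records the
#'   precision at which each rate was printed.
#' * `table1_counts` — overexposed-group comorbidity counts from the
#'   baseline table (CKD 38/137, CHF 19/137). These disagree with the
#'   stratum counts above (39/41 CKD, 20/21 CHF imply 39 and 20 overexposed
#'   patients); the source is internally inconsistent and both versions are
#'   kept, labelled by origin.
#' * `cohort_spec` — see [default_cohort_spec()].
#' * `hierarchy` — the full reference hierarchy: criterion-weight override
#'   plus the scheme matrix under every criterion, ready for [ahp()].
#'
#' @return A named list of fixtures (see Details).
#' @examples
#' fx <- reference_fixtures()
#' fx$scheme_matrix
#' @export
reference_fixtures <- function() {
  scheme <- judgment_matrix(
    list(c(1, 7, 7),
         c("1/7", 1, "1/2"),
         c("1/7", 2, 1)),
    labels = c("increasing dose", "increasing interval", "delaying infusion"),
    strict_scale = TRUE)

  criterion_weights <- c(APTT = 0.0584, OI = 0.1899, CHF = 0.1614, CKD = 0.5902)

  strata <- data.frame(
    stratum = c("moderate/severe CKD", "CHF", "OI < 245", "OI >= 245",
                "APTT > 33.65 s", "APTT <= 33.65 s"),
    n = c(41L, 21L, 112L, 82L, 131L, 63L),
    k = c(39L, 20L, 93L, 50L, 107L, 32L),
    digits = c(2L, 2L, 0L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)

  h <- hierarchy(
    goal = "vancomycin trough overexposure",
    alternative_matrices = list(APTT = scheme, OI = scheme,
                                CHF = scheme, CKD = scheme),
    criterion_weights = criterion_weights)

  list(scheme_matrix = scheme,
       criterion_weights = criterion_weights,
       criterion_consistency = list(ci = 0.0796, cr = 0.0885),
       strata = strata,
       table1_counts = data.frame(
         variable = c("CKD", "CHF"),
         overexposed_with = c(38L, 19L),
         overexposed_total = c(137L, 137L),
         compliant_with = c(3L, 2L),
         compliant_total = c(57L, 57L),
         stringsAsFactors = FALSE),
       cohort_spec = default_cohort_spec(),
       hierarchy = h)
}

#' Default synthetic cohort specification
#'
#' The two-group marginal structure of the reference cohort (57 compliant /
#' 137 overexposed): mean +/- SD variables modelled normal, median \[IQR\]
#' labs modelled log-normal matched by quartiles, comorbidities binary at
#' the per-group prevalences. Parameter values are the published group
#' summaries.
#'
#' @return A [cohort_spec()] in fixed-margins mode.
#' @export
default_cohort_spec <- function() {
  ln <- function(median, q1, q3) list(median = median, q1 = q1, q3 = q3)
  nm <- function(mean, sd) list(mean = mean, sd = sd)
  bn <- function(prev) list(prev = prev)
  vars <- list(
    variable_spec("age", "normal", nm(59.79, 13.54), nm(65.55, 14.45)),
    variable_spec("weight", "normal", nm(67.33, 12.08), nm(62.93, 11.48)),
    variable_spec("albumin", "normal", nm(32.34, 6.02), nm(31.27, 6.12)),
    variable_spec("apache2", "normal", nm(19.42, 6.81), nm(21.38, 6.51)),
    variable_spec("pct", "lognormal", ln(1.06, 0.39, 4.02), ln(4.06, 0.74, 25.55)),
    variable_spec("pt", "lognormal", ln(14.40, 13.30, 15.95), ln(15.50, 13.90, 18.70)),
    variable_spec("aptt", "lognormal", ln(32.70, 29.15, 37.20), ln(37.00, 33.95, 43.60)),
    variable_spec("inr", "lognormal", ln(1.16, 1.08, 1.27), ln(1.26, 1.14, 1.50)),
    variable_spec("un", "lognormal", ln(8.84, 5.40, 15.42), ln(12.76, 7.80, 20.30)),
    variable_spec("oi", "lognormal", ln(262.50, 172.67, 322.16), ln(204.00, 154.00, 283.33)),
    variable_spec("male", "binary", bn(0.8772), bn(0.7372)),
    variable_spec("crrt", "binary", bn(0.1930), bn(0.3358)),
    variable_spec("septic_shock", "binary", bn(0.2982), bn(0.4963)),
    variable_spec("heart_disease", "binary", bn(0.1228), bn(0.2701)),
    variable_spec("chf", "binary", bn(0.0351), bn(0.1387)),
    variable_spec("ckd", "binary", bn(0.0526), bn(0.2773)))
  cohort_spec(vars, n_compliant = 57L, n_overexposed = 137L)
}
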