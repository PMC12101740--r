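Package: vancahp
Title: Risk-Factor Screening and Analytic Hierarchy Process Ranking for
    Vancomycin Trough Overexposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for identifying and ranking risk factors
    of supra-therapeutic vancomycin trough concentrations in mechanically
    ventilated intensive-care patients. Provides an analytic hierarchy
    process (AHP) engine with exact-rational Saaty judgment matrices,
    priority-weight extraction (column normalisation and principal
    eigenvector), lambda-max consistency analytics (CI, simulated or
    tabulated RI, CR), hierarchical total ranking and an inverse search
    recovering judgment matrices from target weights; a synthetic two-group
    cohort generator matched to published marginal summaries; univariate
    screening (Welch t, Wilcoxon rank-sum, chi-square/Fisher) with a
    significance gate; multivariable logistic regression by iteratively
    reweighted least squares with Wald odds-ratio intervals; and ROC curve
    construction with Youden-index optimal cutoffs and cutoff-stratified
    overexposure rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
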