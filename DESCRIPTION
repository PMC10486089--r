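Package: claimsagree
Title: Agreement Between Claims-Based and Self-Reported Asthma Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing chronic-disease status ascertained from
    administrative health data (physician billing claims and hospitalizations
    with ICD-9/ICD-10 diagnosis codes) against self-report, under a stratified
    balanced survey design. Implements a family of claims-based asthma
    case-ascertainment algorithms with configurable time windows over a
    30-year lookback, inverse-probability design weights, weighted 2x2
    agreement statistics (overall agreement, Cohen's kappa, positive and
    negative agreement) with large-sample confidence intervals, weighted
    logistic regression with linearized (sandwich) variance and purposeful
    variable selection, Rubin-pooled multiple imputation for categorical
    covariates, misclassification sensitivity scenarios, and a seedable
    synthetic birth-cohort generator emulating the study design so that the
    whole pipeline is testable without access to confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    sandwich,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
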