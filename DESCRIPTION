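Package: drcohort
Title: Doubly Robust Risk-Ratio Analysis of Blood Pressure Categories in
    Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the association between systolic blood
    pressure categories and cardiovascular risk in observational
    electronic health record (EHR) cohorts, with chronic obstructive
    pulmonary disease cohorts as the motivating setting. Provides a
    synthetic longitudinal EHR generator with a latent multimorbidity
    confounder and known ground-truth marginal risk ratios; an
    exposure-window cohort builder (blood pressure cleaning and
    averaging, six exposure categories, outcome ascertainment, selection
    flowchart); a doubly robust (AIPW) marginal risk-ratio estimator
    driven by a sequence encoder over longitudinal diagnosis and
    medication tokens with propensity and outcome heads; a conventional
    comparator based on logistic regression, chained-equation multiple
    imputation and direct standardisation with Rubin pooling; and the
    associated sensitivity analyses, cohort descriptives and forest
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
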