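Package: gdmscreen
Title: First-Trimester Selective Screening for Gestational Diabetes:
    Prognostic Models Versus a Single-Risk-Factor Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the rule-based single-risk-factor approach used in
    first-trimester selective screening for gestational diabetes mellitus
    (GDM) against published first-trimester logistic prognostic models that
    are recalibrated (calibration slope and intercept) and extended with a
    natural-log transform of random venous glucose. Provides a synthetic
    maternal cohort generator matched to published cohort marginals,
    chained-equations multiple imputation with Rubin's-rules pooling,
    discrimination and calibration metrics, decision-curve analysis
    (net benefit), fixed-operating-point screening scenarios and
    reclassification tables, and an end-to-end seeded pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2
Config/testthat/edition: 3
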