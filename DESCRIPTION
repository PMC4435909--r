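Package: prevalid
Title: External Validation of Prevalent Diabetes Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the external validation of risk prediction models for
    prevalent undiagnosed type 2 diabetes in a new population. Risk models are
    declared as editable coefficient files and evaluated on participant-level
    cohort data; performance is summarised by discrimination (concordance
    statistic with DeLong confidence intervals and paired comparisons),
    calibration (expected/observed ratio with Poisson intervals, calibration
    curves, Brier score, Yates slope) and Youden-index threshold statistics,
    overall and in subgroups. Models can be recalibrated to the validation
    population by intercept adjustment, and a chained-equations multiple
    imputation sensitivity analysis re-runs the validation on completed
    datasets. A synthetic cohort generator reproduces the covariate structure
    of a community-based oral glucose tolerance test screening sample so the
    whole pipeline can be exercised end to end without access to the original
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
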