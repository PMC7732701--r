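Package: deprisk
Title: External Validation and Updating of an Adolescent Depression Risk Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transporting a penalized logistic risk model for
    adolescent depression to a new cohort and assessing its performance.
    Implements raw-survey predictor coding (DSM-IV depression classification,
    maltreatment, drug use, social isolation, fights), ridge-penalized
    maximum-likelihood logistic fitting, and a full discrimination and
    calibration panel (Brier score, AUC with stratified bootstrap confidence
    intervals, calibration-in-the-large, calibration slope, a 2-df
    unreliability likelihood-ratio test, and flexible calibration curves)
    under standard, intercept-adjusted, and refitted validation regimes.
    Includes a synthetic two-cohort generator with a prevalence shift and a
    sample-selection audit trail so the whole pipeline runs end to end
    without access to the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    glmnet,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
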