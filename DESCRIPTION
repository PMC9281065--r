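Package: hemodyn
Title: Validation Toolkit for Hemodynamic-Instability Early-Warning Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to externally validate early-warning scores for
    hemodynamic instability in intensive care. Annotates instability
    onsets from intervention logs (vasoactive administration,
    cumulative-volume fluid therapy, blood-product transfusion rules),
    extracts hourly lead-time-indexed feature samples with plausibility
    filtering, staleness-limited last-observation-carried-forward and
    clinical fallback imputation, fits a retrainable tree-ensemble risk
    score that tolerates missing inputs, and evaluates discrimination
    (AUROC with DeLong confidence intervals and paired tests,
    time-varying by hours before onset), alarm thresholds, lead time,
    false-alarm rates, calibration and case-mix shift. Includes a
    synthetic ICU cohort generator with a latent deterioration signal so
    the whole pipeline is testable against closed-form expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
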