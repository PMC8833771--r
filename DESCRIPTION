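Package: landmarkDPM
Title: Dynamic Prediction of Survival by Spline-Smoothed Landmarking
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits spline-smoothed landmark Cox supermodels for dynamic
    prediction of survival from irregularly measured longitudinal
    predictors. Covariate effects vary smoothly over landmark time through
    a compactly supported (Wendland) basis expansion, baseline hazards are
    stratified by landmark, and standard errors are cluster-robust by
    patient. Includes inverse-probability-of-censoring-weighted (IPCW)
    time-dependent AUC with patient-wise bootstrap inference, model-based
    calibration via offset Poisson regression on martingale residuals, a
    longitudinal cohort simulator for validation, and a command-line
    pipeline chaining simulation, landmarking, fitting, evaluation and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
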