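Package: fluidroc
Title: Gray-Zone ROC Evaluation of Dynamic Preload Indices for Fluid
    Responsiveness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate functional hemodynamic parameters (stroke
    volume variation, pulse pressure variation, pleth variability index)
    as predictors of fluid responsiveness in mechanically ventilated
    patients. Computes the indices from beat-by-beat series with
    device-specific time windows, classifies fluid-challenge responders
    by relative stroke volume increase, and fits per-index ROC analyses
    with area under the curve, Youden-optimal thresholds, and two
    gray-zone (inconclusive interval) estimators: a stratified bootstrap
    confidence interval of the optimal threshold and a diagnosis-tolerance
    two-graph ROC band, the wider being final. Includes pairwise AUC
    comparison by a z-test on Hanley-McNeil standard errors, power and
    sample-size design for the fluid-challenge study, and a synthetic
    cohort and beat-series generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
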