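Package: lekaccel
Title: Accelerometer-Based Analysis of Temperature Effects on Lekking
    Display Behaviour
Version: 0.1.0
Authors@R:
    person("Movement Ecology", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how ambient temperature shapes the display
    behaviour of lekking birds tracked with tri-axial accelerometers.
    Provides a calibrated synthetic biologging generator with known ground
    truth, per-burst summary-statistic feature extraction, cross-validated
    behaviour classification (random forest, decision tree, k-nearest
    neighbours, linear support vector machine), behaviour-budget
    aggregation with the study-design temporal filters, smooth additive
    mixed models of display probability and daily display activity against
    temperature, and counterfactual warming-scenario projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14),
    mgcv,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
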