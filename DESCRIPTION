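Package: glucodss
Title: Interpretable Glucose Forecasting and Replay-Based Decision Support for Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying interpretable blood-glucose prediction and
    corrective-insulin-bolus decision support in type 1 diabetes. Provides a
    glucose-insulin minimal-model simulator with subcutaneous insulin and oral
    carbohydrate absorption compartments, a synthetic-data generator that
    emulates continuous glucose monitoring (CGM) corpora with meal/bolus
    collinearity, sensor noise and data gaps, two LSTM forecasters (with and
    without a physiological insulin-on-board/carbs-on-board preprocessing
    layer), exact and kernel-estimated Shapley-value attribution of forecasts
    to input channels, standard forecast-accuracy and time-in-range metrics,
    and an identify-then-replay engine that re-simulates postprandial windows
    under a corrective-bolus policy driven by the trained forecasters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
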