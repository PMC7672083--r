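Package: fireardl
Title: ARDL Bounds Cointegration and Dynamic Shock Simulation for Fire-Climate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attributing grassland area burned to climatic drivers with
    monthly time series: unit-root and stationarity testing (ADF, Phillips-Perron,
    KPSS, DF-GLS) with integration-order classification, VAR-based lag selection by
    five information criteria, the ARDL bounds F-test for a level (cointegrating)
    relationship with Monte-Carlo simulated critical bounds, least-squares
    estimation of the error-correction ARDL with a residual diagnostic battery and
    recursive CUSUM stability assessment, and stochastic counterfactual simulation
    of the fitted model under one-standard-deviation shocks to a single regressor,
    summarised as percentile fan charts with an equilibrium-shift verdict. A
    synthetic monthly fire-climate data generator with known integration orders,
    cointegrating vector and adjustment speed makes the whole chain testable
    end-to-end without access to observational records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
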