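Package: lakegw
Title: Radon-Based Estimation of Groundwater Discharge and Methane Inputs to Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating lacustrine groundwater discharge and associated
    methane (CH4) inputs from radon-222 tracer surveys. Implements a steady-state
    222Rn mass balance over seven flux terms (sediment diffusion, inlet and outlet
    streams, in-situ 226Ra production, atmospheric evasion, radioactive decay, and
    groundwater), wind-based gas transfer velocity models with exponential wind
    weighting, Monte-Carlo endmember resampling for uncertainty in groundwater
    inflow and CH4 loading, a lake CH4 budget with ebullition scaling, spatial
    driver statistics (Spearman collinearity screening, NIPALS partial least
    squares with VIP scores, all-subsets AIC regression), and a calibrated
    synthetic survey generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
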