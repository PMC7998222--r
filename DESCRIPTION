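Package: vitipheno
Title: Thermal-Time Phenology Models for Grapevine Budburst and Flowering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and validation of daily temperature-based phenology
    models for grapevine (Vitis vinifera) budburst (BBCH 09) and flowering
    (BBCH 61). Implements three daily forcing-rate formulations (growing
    degree-days above a base temperature, a triangular response over cardinal
    temperatures, and the UniFORC sigmoid), thermal-time accumulation from a
    start day to a critical forcing total, Metropolis simulated-annealing
    parameter estimation with multi-start parameter ranges, goodness-of-fit
    metrics (model efficiency, RMSE, mean absolute deviation, regression
    through the origin, difference-class frequencies), a multistep
    per-variety calibration / cross-variety validation / pooled global-model
    workflow, and a seeded synthetic-data generator emulating a multi-season,
    multi-variety vineyard observation design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
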