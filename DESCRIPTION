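Package: thermoskin
Title: Benchtop Thermal Skin Model Analysis for Contact Skin Temperature Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying measurement error of contact skin-temperature
    sensors on a benchtop thermal skin model. Simulates a silicone skin simulant
    as a pair of one-dimensional thermal resistance networks (disturbed and
    undisturbed columns), generates rig and human-trial datasets with realistic
    sensor noise and quantization, identifies calibration steady states and fits
    per-sensor linear corrections, extracts per-step steady-state means,
    extrapolates subsurface reference readings to the surface via Fourier's law,
    computes local temperature disturbance and two forms of sensor bias with
    fixed-temperature summaries and unadjusted t-based confidence intervals, and
    implements an inverse-prediction procedure for comparing sensor types at
    common reference temperatures, including weighted-mean skin temperature,
    vapor-pressure and sweat-onset calculations for human trials.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
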