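Package: pmcalibrate
Title: Spatial Calibration and Mapping of Dense Low-Cost PM2.5 Sensor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibrates dense networks of low-cost PM2.5 sensors against
    sparse reference-grade regulatory stations. Collocates each station with
    its nearest sensor, fits both a global linear calibration and a
    kernel-weighted spatially varying-coefficient (geographically weighted)
    calibration with Gaussian-kernel bandwidth selected by leave-one-out
    cross-validation, and interpolates calibrated concentrations onto a
    regular grid by inverse distance weighting. Includes a synthetic network
    generator with a known truth field and spatially heterogeneous sensor
    bias, full residual/fit diagnostics, and a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
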