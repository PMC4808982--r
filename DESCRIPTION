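Package: cumulair
Title: Cumulative Air-Pollution Exposure Assessment with Residential Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing cumulative long-term exposure to an air
    pollutant (such as NO2) at a fine spatial scale in semi-ecological
    epidemiological studies. Spatial units (census blocks) and fixed
    monitoring stations are grouped by hierarchical clustering of their
    annual concentration profiles so that each unit receives an "index"
    monitor; unit-level annual means are then reconstructed for years
    before the modelled period through a log-log calibration of each unit
    on its index monitor; finally, cumulative exposure over a disease
    latency window is computed with and without residential mobility, the
    latter via row-stochastic residence-transition matrices with an
    absorbing outside-area category. Includes a synthetic-data generator
    emulating the assumed data regime (cluster-specific log-linear trends,
    seasonal daily monitor series, spatially structured mobility), a
    hold-out validation scheme for the reconstruction error, tidy
    accessors, and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
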