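Package: apd
Title: Hierarchical Bayesian State-Space Models for Adelie Penguin Colony Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits a hierarchical Bayesian state-space model to sparse,
    irregular census time series of Adelie penguin breeding colonies
    (nest and chick counts with coded census accuracy), partitioning
    variation in population growth rates into sea-ice covariate effects,
    continent-wide year effects, and process error, while propagating
    multiplicative observation error.  Latent abundances are imputed for
    unsurveyed seasons and hindcast to the start of the study period, and
    posterior abundance can be aggregated over management regions.  Includes
    forward simulation of the full generative model for synthetic datasets,
    simulation-based calibration checks, and a power study of how process
    noise limits the detection of population trends from single or
    aggregated census series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
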