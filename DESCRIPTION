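Package: iguanaharvest
Title: Bayesian State-Space Logistic Modelling of a Harvested Invasive
    Iguana Population
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a Bayesian state-space logistic (surplus-production) model
    to annual survey-based abundance estimates of the invasive green iguana
    (Iguana iguana) on Grand Cayman, with known per-interval harvest rates.
    Provides a seeded adaptive Metropolis-within-Gibbs sampler for carrying
    capacity K, maximum intrinsic growth rate r_max and process noise, derived
    quantities (maximum sustained harvest rate h_msy = r_max/2, doubling
    time), forward Monte Carlo projection of abundance under uniform
    harvest-rate scenario bands, a synthetic-study generator with a
    parameter-recovery harness, lognormal confidence-interval utilities, and
    tidy/ggplot2 interfaces for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
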