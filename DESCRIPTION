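Package: gentimefix
Title: Fixation Probability of Generation-Time Mutants in Changing
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Time-dependent Galton-Watson branching-process machinery for
    the fixation probability of beneficial mutations that shorten the
    generation time rather than increase fecundity. Provides probability
    generating function algebra for serial-passage growth and bottleneck
    sampling stages, the extra-generation schedule that realises a
    generation-time advantage, an effective-selective-advantage
    perturbation approximation with geometric weights, closed forms for
    four environmental scenarios (monotone and cyclic selection,
    Beverton-Holt demography, AR(1) stochastic selection), exact numeric
    iteration of the time-inhomogeneous extinction recursion, and a
    seeded Monte Carlo lineage simulator used as an independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
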