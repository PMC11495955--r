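Package: ceeresp
Title: Behavioural Response Analysis for Controlled Sonar Exposure Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing group-level behavioural responses of dolphins
    to mid-frequency active sonar in controlled exposure experiments (CEEs)
    with a before-during-after phase design. Provides a synthetic CEE data
    generator (Ornstein-Uhlenbeck movement tracks with regime switching,
    zero-heavy whistle counts, tiled subgroup counts, sonar ping logs),
    received-level and cumulative sound-exposure-level arithmetic, a two-state
    latent Bayesian model fitted per response variable by Metropolis-within-Gibbs
    MCMC with phase-specific enhancement probabilities, response and persistence
    probabilities with detection flagging, and a hierarchical dose-response
    regression of movement-response probability on maximum received level and
    pre-exposure speed with truncated-normal errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
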