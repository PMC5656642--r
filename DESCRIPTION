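Package: tigerflux
Title: Car-Mediated Dispersal Flux of the Asian Tiger Mosquito
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates passive dispersal of Aedes albopictus in passenger
    cars from roadside vacuum-sampling surveys, and propagates the
    resulting transport-probability posterior into inter-province
    mosquito flux estimates via commuter origin-destination flows.
    Includes rare-event Bayesian logistic regression with Cauchy priors
    (adaptive Markov chain Monte Carlo with a deterministic quadrature
    oracle), Pareto-smoothed importance-sampling leave-one-out model
    comparison, recapture-efficiency rescaling of posterior draws,
    area-weighted downscaling of gridded prevalence posteriors to
    municipalities, commuter-flow flux aggregation with sample-based
    uncertainty propagation, and a seeded synthetic-data generator for
    every pipeline input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
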