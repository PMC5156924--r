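Package: transmitr
Title: Simulation-Based Inference of Frequency-Dependent Cultural Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative models of frequency-dependent cultural transmission
    (conformist, unbiased and anti-conformist copying with infinite-alleles
    innovation) producing time-averaged archaeological assemblage samples
    under equilibrium and non-equilibrium regimes, coupled to approximate
    Bayesian computation rejection inference. Provides an event-based
    simulation core with a sliding-window social-information pool, three
    model versions (equilibrium, variable population, variable
    population-transmission mode), version-specific euclidean distances,
    posterior summaries (median and highest posterior density intervals),
    posterior predictive checks, and a synthetic-data generator emulating
    Neolithic pottery motif count sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
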