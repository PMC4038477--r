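Package: clocksig
Title: Circadian Oscillator Phenotyping, Core-Clock Modelling and
    Clock-Cancer Gene Signatures
Version: 0.1.0
Authors@R:
    person("clocksig", "maintainers", email = "clocksig@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising circadian oscillators in cancer cell
    lines and linking clock deregulation to oncogenic signalling. Provides
    running-average detrending and smoothing of bioluminescence reporter
    traces, damped-cosine rhythm fitting with strong/weak oscillator
    classification, entrainment-phase estimation and delta-delta-CT qPCR
    quantification; a self-contained two-loop core-clock ODE model with a
    global BMAL1-transactivation scaling factor, limit-cycle feature
    extraction, period/magnitude control-coefficient analysis and an
    antipodal Per/Cry perturbation screen; empirical-Bayes moderated
    t-statistics with leave-one-out cross-validated gene-signature
    discovery, clustering validation and binomial classification testing;
    gene-interaction network assembly with citation-bin-matched random-set
    nulls for cross-set connectivity enrichment; and seeded synthetic-data
    generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
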