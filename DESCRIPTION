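Package: optidend
Title: Optimal Spike-Based Synaptic Integration and Nonlinear Dendrite Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how postsynaptic neurons should integrate
    presynaptic spike trains when the computation they perform is defined on
    the analog activities (membrane potentials or firing rates) that generated
    those spikes. Provides a generative simulator of correlated presynaptic
    population activity (two-state Markov switching of cell assemblies on top
    of multivariate Ornstein-Uhlenbeck membrane-potential fluctuations with
    exponential-link Poisson spiking), an assumed-density filter computing the
    Bayes-optimal postsynaptic response to observed spike trains, a particle
    filter used as an independent oracle for the posterior, a family of
    simplified nonlinear-dendrite models (linear, somatic-nonlinearity, random
    and clustered two-layer subunit models, and a reduced sigmoidal
    integrator), least-squares model fitting and cross-validated benchmarking,
    and a pipeline for fitting the optimal response to glutamate-uncaging
    style stimulation protocols and recorded voltage traces with BIC model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
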