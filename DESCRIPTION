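Package: specdcm
Title: Spectral Dynamic Causal Modeling of Resting-State fMRI with
    Functional-Connectivity Priors and Bayesian Model Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates large directed, weighted, signed graphs of effective
    connectivity from resting-state BOLD fMRI time series.  Implements the
    spectral variant of dynamic causal modeling: a linear stochastic neural
    model with power-law endogenous fluctuations and a linearized
    balloon-Windkessel hemodynamic observation model, fitted to observed
    complex cross-spectral densities by variational Laplace (Gauss-Newton
    free-energy ascent).  Prior covariance over coupling parameters can be
    rank-reduced onto leading functional-connectivity modes via a Kronecker
    projector, and Bayesian model reduction scores reduced priors
    analytically, supporting both mode-number selection and per-edge pruning
    of the coupling matrix.  Includes a ground-truth simulator (stable
    coupling matrices, spectrally shaped fluctuations, nonlinear balloon
    hemodynamics, observation noise), directed-graph summaries
    (in- and out-strength, symmetric and antisymmetric split, network
    down-sampling, group binarized averages), plain-text I/O, and a
    command-line workbench.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
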