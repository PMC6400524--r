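Package: ebmetad
Title: Ensemble-Biased Metadynamics for Distance-Distribution Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bias a stochastic model of a spin-spin distance coordinate so that
    its sampled ensemble reproduces a target distance distribution, such as one
    measured by pulsed electron-electron double resonance (DEER/PELDOR), and
    score how compatible a starting conformation is with those data.  Provides
    ensemble-biased metadynamics (EBMetaD) on a one-dimensional collective
    variable over analytic toy potentials, the work functional based on the
    time-averaged bias (equivalently kT times the Kullback-Leibler divergence
    between biased and debiased ensembles), debiasing and range-restricted work,
    split-half uncertainties, per-feature decomposition of the work, Gaussian
    preprocessing of multi-peak distance distributions, coordination-number
    restraints, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
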