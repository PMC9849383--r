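Package: skipotential
Title: Bayesian Potential Estimation and Progression Typologies for
    Lower-is-Better Longitudinal Performance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual performance potential from longitudinal
    age-performance records scored on a lower-is-better points scale (such
    as FFS/FIS alpine-skiing race points). Fits a Bayesian hierarchical
    Moore-type double-exponential growth/decline curve with per-individual
    random effects using a No-U-Turn Hamiltonian Monte Carlo sampler,
    producing per-individual potential curves with estimate intervals and
    peak-age/peak-performance summaries. Individuals are then clustered
    into progression typologies with Gaussian mixture models over a
    14-member covariance parameterization family, selected by a
    kernel-density overlap score on progression-slope distributions, and
    each individual receives probabilistic cluster membership with
    uncertainty propagated through the posterior draws. Includes a
    synthetic-cohort generator with known ground truth and a pipeline
    runner for end-to-end reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
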