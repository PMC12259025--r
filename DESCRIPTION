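Package: corrddm
Title: Correlation-Aware Evidence Weighing and Drift-Diffusion Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how decision-makers should and do weigh
    pairwise-correlated evidence. Implements the ideal-observer
    log-likelihood ratio for correlated bivariate Gaussian observations and
    its correlation-dependent scale factor, a generative task simulator
    (trial designs, adaptive 3-down-1-up staircase calibration, stimulus
    streams, and synthetic drift-diffusion observers), a family of
    drift-diffusion model variants with correlation-dependent drift and
    collapsing-bound scaling, a Crank-Nicolson first-passage-time solver
    with a path-simulation oracle, maximum-likelihood fitting of full
    choice and response-time distributions by differential evolution,
    and random-effects Bayesian model selection with protected exceedance
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
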