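Package: qtlmix
Title: Dirichlet Process Gaussian Mixture Modelling of QTL Effect
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the distribution of quantitative trait locus (QTL)
    additive effects and dominance coefficients with a Dirichlet process
    Gaussian mixture model (DPGMM) that accounts for the known standard
    error of every observed effect. Cluster membership follows a Chinese
    restaurant process and all unknowns are updated by Gibbs sampling
    with conjugate normal and inverse-gamma conditionals. Includes the
    meta-analysis preprocessing used to combine effects across studies
    (phenotypic-standard-deviation scaling, sign doubling, delta-method
    standard errors for dominance coefficients, standard errors from LOD
    scores or replicate experiments), posterior summaries with Bayesian
    credible intervals, truncated-mixture simulators for validating
    recovery of the number of components, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
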