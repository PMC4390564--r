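Package: epivar
Title: Bayesian Estimation of Transgenerational Epigenetic Variance from
    Pedigrees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Linear mixed ("animal") models extended with a heritable
    transgenerational epigenetic effect whose covariance across a pedigree is
    described by an epigenetic relationship matrix T that depends on a single
    autorecursive parameter lambda (equivalently a reset coefficient
    v = 1 - 2*lambda). Provides pedigree reading and validation, Henderson's
    rules for the inverse numerator relationship matrix, one-pass rules for
    the sparse inverse of T, a Gibbs sampler for all location effects,
    variance components and lambda (with a truncated-normal update and an
    exact Metropolis-within-Gibbs variant), a population simulator matching
    the model's covariance structure, posterior summaries, convergence
    diagnostics, and model comparison by the logarithm of the conditional
    predictive ordinate (LogCPO).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
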