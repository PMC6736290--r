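Package: phylovenom
Title: Macroevolution of Snake Venom Composition via Phylogenetic Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing the macroevolution of compositional
    gene-expression phenotypes such as snake venom. Estimates a phylogenetic
    covariance (PCOV) matrix and per-component phylogenetic signal (lambda)
    with a Bayesian multivariate phylogenetic mixed model (the animal model
    with a phylogeny in place of a pedigree, fit by a blocked Gibbs sampler),
    projects species into a phylomorphospace by eigen-analysis of the PCOV,
    detects convergent adaptive regimes with a stepwise AICc search over
    Hansen (Ornstein-Uhlenbeck) models plus a simulated null distribution,
    and reconstructs ancestral toxin abundances by maximum likelihood.
    Includes compositional-data utilities (percent normalisation, prevalence
    filtering, multiplicative zero imputation, centred log-ratio transform)
    and a synthetic-data generator with the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
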