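Package: pagelion
Title: Correlated Evolution of Binary Traits on Phylogenies
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood and Bayesian analysis of discrete binary
    characters on time-calibrated phylogenies, built around Pagel's test of
    correlated evolution for trait pairs. Provides Mk (ER/ARD) model fitting
    with likelihood-ratio tests and AIC weights, 4-state dependent/independent
    rate matrices with structurally forbidden double transitions, Felsenstein
    pruning likelihoods that handle multifurcations and missing data, marginal
    ancestral-state reconstruction, stochastic character mapping, replication
    of the independent-vs-dependent comparison over bootstrap tree sets,
    reversible-jump MCMC over rate-class structures with an exponential
    hyperprior, stepping-stone marginal likelihoods and Bayes factors on the
    2*delta-log scale, and effective-sample-size diagnostics. Includes
    birth-death tree and forward CTMC trait simulators, bootstrap-style tree
    set perturbation, and tallying of multi-organ presence/absence surveys
    such as androconial organ inventories in Eumaeini butterflies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
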