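Package: mlggm
Title: Multilevel Bayesian Gaussian Graphical Models with a Curie-Weiss Group Level
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly estimates one network per participant and a shared group-level
    network from multivariate time series. Individual-level networks are Gaussian
    graphical models with a spike-and-slab prior on the precision matrix; the
    group level is a Curie-Weiss model over the edge-inclusion indicators, so that
    individual networks are conditionally independent given the group. Includes a
    Gibbs sampler for the joint model, individual-only and aggregated baseline
    estimators, an exact simulator for the full generative process (Curie-Weiss
    graphs, G-Wishart precision matrices, Gaussian time series), and evaluation
    statistics: ROC/AUC edge recovery, inclusion Bayes factors, group-to-individual
    prediction with confidence bands, heterogeneity variance, and convergence
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
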