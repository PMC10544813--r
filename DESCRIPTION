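Package: probitNNGP
Title: Scalable Prediction for Spatial Probit Linear Mixed Models via
    Nearest-Neighbour Gaussian Processes
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits and predicts from spatial probit linear mixed models for
    point-referenced binary data (species presence-absence records and
    similar) without Markov chain Monte Carlo. The marginal likelihood of
    the binary response vector is a high-dimensional multivariate normal
    cumulative distribution function; its covariance is approximated with a
    Nearest-Neighbour Gaussian Process (Vecchia) factorisation whose
    Cholesky columns are recovered by sparse triangular solves, and the
    resulting integrals are evaluated with the separation-of-variables
    Monte-Carlo estimator. Includes grid-search estimation of the spatial
    variance and decay, batch out-of-sample prediction of presence
    probabilities with Monte-Carlo standard errors, a geostatistical
    simulation harness, and dense reference implementations for validation
    at small sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
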