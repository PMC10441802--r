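Package: bmaclust
Title: Bayesian Model Averaging of Cluster Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines cluster allocations from multiple unsupervised
    clustering algorithms through Bayesian model averaging. Each input
    solution is weighted by a normalised clustering internal validation
    index (Calinski-Harabasz or S_Dbw) approximating its posterior model
    probability, per-model pairwise similarity matrices are averaged into
    a consensus matrix, and symmetric simplex matrix factorisation of the
    consensus yields probabilistic allocations to averaged clusters with
    a per-observation measure of model-based uncertainty. Includes uniform
    adapters for nine standard clustering algorithms, a multivariate
    normal cluster simulator with a controllable quantile-based separation
    index, and a benchmarking harness based on the adjusted Rand index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    class,
    kernlab,
    mclust,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
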