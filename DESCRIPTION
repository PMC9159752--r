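Package: actionrsa
Title: Representational Similarity, Multiple Arrangement, and Time-Resolved
    Decoding of Naturalistic Action Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual, action, and social-affective
    features shape behavioral and neural representations of observed actions.
    Builds feature representational dissimilarity matrices (RDMs) from rating
    tables, annotations and embeddings; simulates and reconstructs multiple
    arrangement sessions via adaptive lift-the-weakest sampling and inverse
    multidimensional scaling; computes time-resolved neural RDMs by split-half
    pairwise decoding with pseudotrial averaging and multivariate noise
    normalization; and relates data RDMs to model RDMs via Kendall tau-a with
    sign-permutation, omnibus and cluster-sum inference, noise ceilings,
    bootstrap onset estimation, and cross-validated variance partitioning
    (commonality analysis) over predictor groups. Includes a synthetic-data
    generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
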