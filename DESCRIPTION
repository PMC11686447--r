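Package: glygolgi
Title: Stochastic Simulation and Multi-Omic Prediction of N-Glycan
    Processing in the Golgi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the processing of N-glycans on monoclonal antibodies as
    they transit Golgi cisternae, using a Gillespie stochastic simulation
    over a compositional glycan state space, and fits per-enzyme,
    per-cisterna activities to observed glycan profiles by approximate
    Bayesian computation with MCMC (square-difference summary statistic,
    Gelman-Rubin convergence diagnostics, Mann-Whitney comparison of
    posteriors between glycan clusters).  A companion multi-omic workflow
    clusters glycan profiles (PCA, k-means with elbow selection) and
    predicts cluster membership from glycogene transcriptomics at three
    culture time points via a multi-block sparse PLS discriminant model
    with 10-fold cross-validation, ROC/AUC evaluation and stability
    selection of predictive genes.  A synthetic-data generator emulates the
    two-project CHO bioprocess study design (cluster-structured glycan
    profiles, replicated samples, negative-binomial expression blocks with
    planted marker genes) so every step is testable without access to
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    mclust,
    pROC,
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
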