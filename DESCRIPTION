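Package: AirwayNet
Title: Co-Occurrence Network Analysis of the Neonatal Airway Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links microbial co-occurrence network architecture in the
    preterm airway to ordinal disease severity. Provides amplicon count-table
    preprocessing (singleton, organelle, abundance/prevalence filters,
    rarefaction), alpha and beta diversity statistics with permutation
    inference, a from-scratch compositionally robust (SparCC) correlation
    estimator with resampling-based edge significance, per-group network
    construction with topology profiling and keystone-taxon scoring,
    permutation-based network comparison including a graph dissimilarity
    measure, a proportional-odds ordinal outcome model with forward stepwise
    covariate selection, and a synthetic cohort generator with planted
    basis-correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    igraph,
    vegan,
    jsonlite,
    matrixStats,
    tools,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
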