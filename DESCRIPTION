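Package: pretermEHG
Title: Preterm Labor Prediction from Multichannel Electrohysterograms
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for predicting preterm labor from
    three-channel electrohysterographic (EHG) recordings and obstetric
    covariates. Extracts 203 temporal, spectral and non-linear features
    (peak-to-peak amplitude, Teager energy, Welch spectral descriptors,
    sample/fuzzy/spectral entropy, Lempel-Ziv complexity, time
    reversibility, Katz fractal dimension and Poincare descriptors) in
    four analysis bandwidths, balances classes by SMOTE, selects feature
    subsets with a genetic-algorithm wrapper whose fitness trades mean
    validation F1 against subset size, and evaluates KNN, LDA and
    logistic-regression base classifiers plus a majority-vote ensemble
    under a repeated stratified holdout protocol with Friedman/Nemenyi
    comparison. Includes a synthetic EHG cohort generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    class,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, Preprocessing, Software
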