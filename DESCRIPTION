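Package: edapain
Title: Real-Time Pain Level Estimation from Electrodermal Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation, preprocessing, feature extraction, classification and
    real-time streaming inference for three-level pain assessment from
    single-channel electrodermal activity (EDA). Provides a synthetic EDA
    cohort generator with ground-truth stimulus annotations, causal
    Butterworth preprocessing with a class-balancing windowing scheme,
    handcrafted time-domain and db4 wavelet features with PCA reduction,
    five classical reference classifiers, a one-dimensional fully
    convolutional network trained with Adam and cross-entropy, subject-wise
    five-fold cross-validation, and a sliding-window streaming estimator
    that emits class/confidence prediction events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    signal,
    MASS,
    nnet,
    rpart,
    e1071,
    xgboost,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
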