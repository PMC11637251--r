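Package: eegms
Title: Resting-State EEG Microstate Segmentation and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis and its use in
    disease classification. Implements global field power (GFP) computation and
    peak selection, polarity-invariant modified K-means clustering of scalp
    topographies with two-level (subject then group) aggregation, canonical A-D
    template ordering, backfitting with temporal smoothing, and extraction of a
    36-dimensional microstate feature set (per-state duration, occurrence,
    coverage, mean spatial correlation, explained variance, and run-wise
    transition probabilities) alongside a 16-dimensional conventional feature
    set (moments, Welch spectral summaries, Hjorth parameters, Petrosian
    fractal dimension, Lempel-Ziv complexity, and approximate/sample/fuzzy
    entropy). Includes a synthetic multichannel EEG generator with planted
    microstate structure, readers for EDF and a plain CSV channel-matrix
    dialect, zero-phase band-pass filtering into the standard delta-gamma
    bands, and a harness comparing SVM, KNN, random-forest and logistic
    classifiers on the two feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    class,
    randomForest,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
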