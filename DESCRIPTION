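Package: epiged
Title: Epileptic Seizure Detection from Single-Channel EEG with Wavelet
    Subband Features and Graph Eigen Decomposition Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seizure/non-seizure classification pipeline for single-channel
    EEG. Segments are cut into overlapping fixed-length frames, decomposed
    into time-domain subband signals by a multilevel discrete wavelet
    transform, and summarised by three spike-related features (second-order
    difference plot ellipse area, squared coefficient of variation of the
    absolute series, fluctuation index) and four entropies (permutation,
    approximate, order-2 Renyi spectral, bispectral phase) per subband.
    Features are ranked by the absolute principal eigenvector of a graph
    adjacency matrix mixing a Fisher-score by mutual-information kernel with
    a pairwise dispersion matrix, and the selected subset feeds a single
    hidden layer tanh/softmax feedforward network evaluated by stratified
    K-fold cross-validation (accuracy, sensitivity, specificity). Includes a
    synthetic EEG generator (1/f background with superimposed transient
    spikes) so the full pipeline runs without any recordings, plus sweep
    utilities over decomposition levels, feature counts and hidden units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
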