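Package: bnpeaks
Title: Bayesian Network Feature Selection for Mass Spectrometry Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Model-free feature selection and classification for
    time-of-flight mass spectrometry peak-intensity tables. Features are
    screened by mutual information with the disease class after a
    three-bin discretization chosen to maximize that mutual information;
    a significance threshold is calibrated against a class-label
    permutation baseline. Selected features are organized into a
    class-rooted Bayesian network: serial chains (class -> parent ->
    child) are detected by large drops in conditional mutual information,
    and the surviving first-level features form a Markov blanket used as
    a smoothed probabilistic classifier. Stability of the selected
    network is assessed by repeated stratified k-fold cross-validation
    with arc-frequency tallies and a consensus network. A synthetic
    peak-table generator with known ground-truth structure (correlated
    child peaks, doubly charged ions, peak convolution, hidden-parent
    fragments) supports structure-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
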