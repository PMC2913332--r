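Package: skinqsar
Title: Global QSAR Classification of Skin Sensitisers from LLNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary QSAR classification of skin sensitisation potential from
    murine Local Lymph Node Assay (LLNA) EC3 potency classes. Computes a
    panel of fourteen topological, connectivity and composition descriptors
    from SMILES, selects descriptor subsets with a hybrid genetic-algorithm /
    stepwise procedure or a cross-correlation and collinearity filter, and
    fits either an Adaptive Fuzzy Partition (AFP) rule-based classifier with
    trapezoidal membership functions or a one-hidden-layer perceptron with
    momentum learning and cross-validation early stopping. Includes a min-max
    descriptor-space applicability domain, stratified splitting, the standard
    confusion-matrix validation statistics, and a synthetic descriptor-table
    generator with planted class structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    nnet,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
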