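Package: neurofuse
Title: Network-Level Fused Dense/Inception CNN with Attention, Catch Fish
    Optimization Feature Selection, and Shallow Classifiers for MRI Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and audits a 115-layer fused convolutional architecture
    (a dense module with self-attention and an inception module with
    multiscale self-attention heads, joined by network-level depth
    concatenation), trains it on class-per-folder 2-D brain images, extracts
    fused deep features at the concatenation layer, selects features with the
    Catch Fish Optimization swarm metaheuristic, and evaluates shallow
    feed-forward classifier variants with stratified k-fold cross-validation.
    Ships a synthetic brain-phantom generator so the full pipeline runs with
    no external data.
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
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
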