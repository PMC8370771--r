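Package: image3c
Title: Image-Based Clustering, Abundance Testing and Classification of
    Imaging Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An open, antibody-free analysis pipeline for imaging flow
    cytometry. Extracts morphological and fluorescence features from
    multi-channel cell images (spillover compensation, background
    subtraction, segmentation, gating), preprocesses feature tables
    (Spearman redundancy trimming, replicate QC, logicle transformation,
    2N/4N DNA landmark normalization, unit-SD scaling), clusters events
    de novo by k-nearest-neighbour density mode seeking with elbow-based
    k selection and force-directed-layout export, tests differential
    cluster abundance with negative binomial regression and
    Benjamini-Hochberg FDR control, and trains a compact DenseNet-style
    convolutional classifier on the de novo clusters so that later
    experiments can be mapped onto the same cell classes. Includes a
    synthetic-data generator that emulates distinct cell populations,
    DNA-content bimodality, intensity drift, spillover, doublets and
    debris, so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
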