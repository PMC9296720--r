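Package: bcttexture
Title: Texture-Based Breast Density Classification for Photon-Counting Breast CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Replicates a radiomics workflow for classifying breast density
    (four-level scale a-d) from coronal breast-CT image stacks. Provides a
    synthetic phantom generator with bimodal fat/gland intensity structure and
    controllable gland volume fraction, polygonal region-of-interest handling
    with a skin-margin erosion, from-scratch computation of 19 first-order,
    grey-level co-occurrence matrix and grey-level run-length matrix texture
    features pooled over multislice examinations, a three-step feature-selection
    cascade (ANOVA with Bonferroni post hoc, Spearman correlation with density,
    correlation-cluster redundancy rejection), a multinomial logistic-regression
    density classifier with stratified 70/30 evaluation, and reader-agreement
    statistics (percent agreement, Cohen's kappa, ICC, per-feature inter-reader
    coefficient of variation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    RNifti,
    jsonlite,
    nnet,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
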