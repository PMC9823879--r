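Package: sczscreen
Title: Schizophrenia Screening from Brain MRI Slices with Mayfly-Selected
    Deep and Handcrafted Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a schizophrenia screening
    pipeline for 2D brain MRI slices. The pipeline strips the skull with a
    threshold filter, separates gray and white matter by mayfly-optimized
    tri-level Otsu thresholding refined with a Markov random field solved
    by iterated conditional modes, extracts gray-level co-occurrence matrix
    descriptors and weighted local binary pattern histograms, selects a
    fixed-size handcrafted feature subset with a mayfly wrapper maximizing
    the between-class Cartesian distance, fuses the result with a reduced
    deep-feature block from a pluggable backbone, and evaluates binary
    classifiers under stratified cross-validation with a full
    confusion-matrix metric suite. A synthetic head-phantom generator makes
    every stage testable without any imaging data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    tiff,
    stats,
    utils,
    rpart,
    nnet,
    e1071,
    xgboost,
    class,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
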