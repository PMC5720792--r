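Package: tumortex
Title: CT Texture Analysis for Two-Year Survival Prediction in Pancreatic Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise radiomic texture analysis of segmented tumors on
    contrast-enhanced CT, built around a 255-feature descriptor combining
    gray-level co-occurrence, run-length, local binary pattern, fractal
    (segmentation-based fractal texture analysis and differential box
    counting), intensity-histogram, and gradient-orientation (angle
    co-occurrence) families. Features are ranked with fuzzy
    minimum-redundancy maximum-relevance selection and evaluated with a
    Gaussian naive Bayes classifier under leave-one-image-out and repeated
    stratified k-fold cross-validation, with selection nested inside every
    training fold. Includes a synthetic tumor-volume generator emulating the
    homogeneous-to-heterogeneous attenuation continuum of pancreatic ductal
    adenocarcinoma so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
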