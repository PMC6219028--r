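Package: ivustex
Title: Intensity-Based Multi-Level Plaque Tissue Classification for
    Intravascular Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise characterization of coronary plaque tissue in
    grayscale intravascular ultrasound (IVUS) frames. Computes 54 windowed
    texture features per plaque pixel (first-order statistics, grey level
    co-occurrence matrix, Laws' energy measures, extended grey level run
    length matrix, raw intensity, and local binary patterns), selects
    per-net feature subsets by principal component loadings, and classifies
    pixels into fibrous tissue, fibro-fatty tissue, necrotic core, and
    dense calcium with an intensity-thresholded cascade of three binary
    random forests. Includes sensitivity/specificity/accuracy and ROC/AUC
    evaluation, and a seeded speckle phantom generator so the whole
    pipeline runs and is tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
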