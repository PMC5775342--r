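Package: sarcotex
Title: Automated Cardiomyocyte Segmentation and Sarcomere Texture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated high-content analysis of multi-channel immunofluorescence
    images of cardiomyocytes and reprogrammed cardiac-like myocytes. Provides
    multi-marker nucleus detection and subtype classification, sequential-masking
    marker-controlled watershed cell segmentation, per-cell morphology metrics,
    and SarcOmere Texture Analysis (SOTA): gray-level co-occurrence matrices
    computed over an angle-by-offset grid inside arbitrary cell masks, Haralick
    texture features, and peak-prominence extraction of sarcomere organization,
    sarcomere length, primary sarcomere direction, and cell-sarcomere
    misalignment. Includes Gabor-filter and Fourier radial-profile comparator
    metrics and synthetic phantom generators with exhaustive ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    tiff,
    png,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
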