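Package: osteoscreen
Title: High-Content RNAi Screen Analysis for Early Osteoblast Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based RNAi screens of early osteoblast
    differentiation in 384-well plates: nuclei segmentation and fluorescent
    alkaline-phosphatase (ELF 97) spot detection on per-field microscopy images,
    per-cell ALP activity quantification, Ki67 positivity, percent-of-control
    plate normalization, z-scoring of binary-logarithmized ALP activity,
    replicate t-testing against Non-Targeting controls, and three-criterion hit
    calling (viability filter, ALP fold thresholds with p-value, z-score margin).
    Includes a synthetic-screen generator that plants per-gene viability and ALP
    effects, places non-overlapping nuclei and punctate ALP spots, and renders
    noisy multi-channel field images with full ground truth, so every stage of
    the pipeline is testable without wet-lab data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    generics,
    ggplot2,
    EBImage,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
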