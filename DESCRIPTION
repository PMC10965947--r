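Package: pdl1bench
Title: Benchmarking Cell-Level PD-L1 Scoring Against Multi-Reader Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking automated PD-L1 cell detection against
    multi-reader point annotations in non-small cell lung cancer
    immunohistochemistry. Implements distance-gated one-to-one ("hit
    criterion") matching of point detections, per-class and macro F1 with
    background-aware confusion matrices, tumor proportion score (TPS)
    quantification and its slide-level agreement battery (linear weighted
    Cohen's kappa at clinical cutoffs, ICC(2,1) with F-based confidence
    intervals, Bland-Altman limits of agreement, majority-vote agreement),
    a two-step semi-automatic annotation pipeline (stain separation,
    Laplacian-of-Gaussian nucleus detection, polygon label transfer), and a
    synthetic multi-reader study generator with closed-form expectations
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    xml2,
    withr,
    generics,
    png,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mgcv
Config/testthat/edition: 3
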