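Package: cvfusion
Title: Multimodal Mechanism-of-Action Profiling for Cell Painting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A toolkit for mechanism-of-action (MOA) classification of
    compound perturbations profiled with the five-channel Cell Painting
    assay. Provides quality-control scoring and filtering of well-level
    image-based profiles, plate-wise control-based normalization (MAD
    robustize, min-max, ZCA-cor spherization), Shapley-ranked feature
    selection with gradient-boosted trees, channel-aware image
    normalization, standardization and augmentation, Morgan-fingerprint
    encoding of compound structures, a three-modality outer-arithmetic
    fusion classifier trained with decoupled weight decay, kBET
    batch-effect scoring, compound-level double-stratified
    cross-validation, and an average-treatment-effect statistic with
    effect-strength buckets. A plate-structured synthetic data generator
    with controllable class signal and batch effects makes the full
    pipeline testable without any external download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    xgboost
Suggests:
    arrow,
    ChemmineOB,
    EBImage,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
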