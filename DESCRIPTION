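Package: wormquant
Title: Quantification of Calcium Transients, Mitochondrial Linearity and
    Amyloid Aggregates in C. elegans Muscle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of three quantification procedures for
    C. elegans body-wall muscle imaging: detection and kinetic
    characterization of spontaneous cytosolic calcium transients from
    dual-emission ratiometric FRET (cameleon YC2.1) recordings using a
    mirror-change acceptance criterion; a 0-200 mitochondrial linearity
    score from random 200-pixel binary line profiles over segmented
    mitochondrial masks, with basic morphology metrics; and Thioflavin-T
    aggregate quantification as the fraction of worm area occupied by
    supra-threshold regions of interest. A synthetic-data module generates
    dual-channel recordings, sarcomere-patterned mitochondrial masks and
    worm aggregate images with known ground truth, so every pipeline stage
    is testable by parameter recovery. Group-level statistics (normality
    check, two-group test, one-way ANOVA with Tukey post hoc) and a
    config-driven batch pipeline are included.
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
    ggplot2,
    generics,
    stats,
    utils,
    zoo,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
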