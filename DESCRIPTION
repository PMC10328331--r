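Package: cepdeg
Title: Automated Quantification of Dopaminergic Dendrite Degeneration in
    C. elegans Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated, unbiased image-analysis pipeline for scoring
    degeneration of the four cephalic (CEP) dopaminergic neurons in
    Caenorhabditis elegans from maximum-intensity-projection fluorescence
    images. Given an image and the camera pixel size in microns, the
    pipeline locates the cell bodies, crops and canonically orients the
    dendrite region, detects bleb-like morphological features by
    noise-adaptive thresholding, horizontal erosion and Chan-Vese contour
    refinement, traces up to four dendrites by per-row ridge tracking,
    detects dendrite breaks, and reports twenty per-dendrite degeneration
    metrics together with a 0-4 categorical degeneration score. A
    synthetic phantom generator with exact ground truth supports
    validation, and cohort-level helpers compute z-scores against a
    control group and one-way ANOVA with Bonferroni or Dunnett correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    multcomp,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
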