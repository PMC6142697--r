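Package: briq
Title: No-Reference Quality Scoring for Structural Brain MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise, no-reference quality assessment of structural brain
    magnetic resonance images. A test slice is normalized (foreground
    extraction, min-max intensity rescaling) and two feature images are
    derived: the grayscale image itself and a local-range-filter contrast
    image. Thresholding each feature image at each of the two first moments
    yields four binary feature images whose structural matching gives four
    attribute scores (luminance contrast, texture, texture contrast,
    lightness) and a weighted total quality index on [0, 1], with volume-level
    aggregation against sequence-specific cut-offs. Includes degradation
    models (circular blur, motion blur, Rician noise, synthetic bias field), a
    two-tissue-class brain phantom generator with ground-truth masks, and a
    Spearman rank-correlation utility for validation against observer scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
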