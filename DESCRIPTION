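Package: wound3ccd
Title: Spectral Index Analysis of RGB Wound Photographs for Predicting
    Dehiscence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts hemoglobin-sensitive spectral indices from
    three-channel (3CCD-style) RGB photographs of traumatic wounds and
    models wound outcome (healed versus dehisced) from them. Provides
    region-of-interest channel statistics with glare/blur/blood quality
    screening, the 14-variable raw and cohort-normalized index set,
    Mann-Whitney group comparisons with false-discovery-rate adjustment,
    diagnostic odds ratios with Woolf confidence intervals, a from-scratch
    NIPALS partial least squares discriminant analysis (PLSDA), a
    sequential two-stage wound classifier with permutation-based
    overfitting control, and a Beer-Lambert synthetic wound-image
    generator for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
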