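Package: neuritequant
Title: Quantification of Neurite Outgrowth, Puncta and RhoA Localization in
    Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for cell-based neurite outgrowth assays in
    NG108-15-style neuronal differentiation models. Detects fluorescent puncta
    and nuclei with an undecimated ("a trous") B3-spline wavelet transform,
    segments micrographs into background/cell/neurite classes with a pixel
    feature bank and an ensemble-of-trees classifier, measures skeleton-based
    neurite length per cell, quantifies nuclear versus cytoplasmic marker
    distribution, and reduces plate-reader (G-LISA RhoA activity, BrdU
    proliferation) and RT-qPCR tables to fold changes with the usual
    ANOVA/Bonferroni statistics. Ships a synthetic fluorescence-scene
    generator with exact ground truth so the whole pipeline is testable
    without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
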