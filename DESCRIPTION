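Package: scleraSHG
Title: Quantitative Analysis of Scleral Crosslinking from Second-Harmonic-Generation Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the effect of scleral tissue crosslinking
    on second-harmonic-generation (SHG) micrographs of collagen fiber bundles.
    Implements the arc-to-chord fiber waviness ratio and the Waviness-%
    statistic with its hierarchical (fiber, image, condition) averaging,
    histogram mean-pixel-density analysis of paired treated/control images
    with paired t-tests and a random-intercept linear mixed model, and the
    16-sector paired thermal-denaturation (delta-Tm) localization analysis.
    Includes a seeded automated ridge tracer for fiber centerlines and a
    fully parameterized synthetic-data generator (wavy bright fiber bundles
    with known arc/chord ratio, condition-dependent brightness, paired-eye
    structure, and per-sector Tm tables) so every pipeline stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
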