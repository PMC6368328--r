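Package: hepaploidy
Title: In Situ Hepatocyte Ploidy Estimation from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-nucleus DNA content and hepatocyte ploidy classes
    (2c, 4c, 8c, 16c) in situ from Hoechst/HNF4a-stained liver tissue images.
    DNA content is computed as mean nuclear Hoechst intensity times an
    interpolated spherical nuclear volume, and calibrated against the
    HNF4a-negative nonparenchymal nuclei within the same tissue as an internal
    2n reference. Includes nuclear segmentation and morphometry, circularity
    and size gating, kernel-density ploidy peak detection, threshold-based
    marker quantification (positive-cell fractions, staining-area and
    co-staining fractions, modal pixel intensity), group summaries with
    two-sample t tests, and a seeded synthetic-tissue generator that produces
    ground-truthed multi-channel images for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
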