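Package: phenogreen
Title: Image-Based Phenotyping of Tissue-Cultured Plants with a CIELAB
    Greenness Index
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation and trait extraction for side-view RGB
    photographs of plants grown in vitro on a blue background. Implements
    a dual-colourspace segmentation pipeline (CMYK yellow channel and
    CIELAB a* channel with morphological cleaning and mask fusion), a
    morphometric trait set (pixel area, convex hull area, perimeter,
    solidity, and the foreground split above and below the culture-medium
    level), and a chromaticity-angle greenness index on a 0-100 scale
    that quantifies verdancy versus chlorosis. Ships a deterministic
    synthetic scene generator with exact ground truth so the whole
    pipeline is testable without photographs, plus batch processing into
    trait and summary tables with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
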