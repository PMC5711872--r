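Package: scarvss
Title: Automated Vancouver Scar Scale Rating from Scar Image Texture and
    Color Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated rating of burn scars on the Vancouver Scar Scale
    (VSS) from digital photographs. Extracts gray-level co-occurrence
    matrix (Haralick-style) statistics, image semi-variograms and local
    binary pattern histograms from grayscale patches together with RGB
    central moments and HSV/CIELAB histograms from the color patches,
    and classifies the VSS total score with one-vs-one error-correcting
    output codes over pluggable binary learners. Includes a leave-one-out
    cross-validation harness, exact and score-tolerance accuracies with
    confusion matrices, and a synthetic colored-texture generator that
    reproduces the study design (8 unbalanced classes, 3x3 sub-image
    expansion) so the full pipeline runs without any clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jpeg,
    jsonlite,
    MASS,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
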