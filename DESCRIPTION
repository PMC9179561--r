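Package: microgliaq
Title: Quantification of Microglial Activation in IBA1 Immunostains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements and compares the three histological read-outs used to
    quantify microglial activation in anti-IBA1 immunohistochemistry: cell
    density (cells per square millimetre), densitometric percent positive
    area after binary thresholding, and cellular morphology via the
    ramification index, the ratio of cell area to convex-hull projection
    area. Includes ROI handling for micrograph rasters, grid-based random
    cell selection, the group-level statistical pipeline (Grubbs' outlier
    screening of densitometry, Kruskal-Wallis with Dunn's post hoc
    comparisons against control), and a synthetic DAB-like scene generator
    with ground truth for parameter-recovery validation on cohorts
    emulating the cuprizone demyelination time course.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
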