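Package: cortexscreen
Title: Screening for Genetic Markers of Cortical Areas by Random-Forest
    Border Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to screen volumetric gene-expression data for genetic
    markers of cortical areas. Three-dimensional in-situ-hybridization-style
    expression volumes, co-registered to an annotation volume with a
    structure hierarchy, are collapsed to two-dimensional surface maps by
    maximum-intensity projection along surface normals (top view or
    flat map). For each cortical area, pixels in a dilated border
    neighborhood are classified as inside or outside the area with a
    Gini-criterion random forest, and genes are ranked by normalized Gini
    variable importance as candidate border markers. A synthetic-atlas
    generator produces curved cortical shells with planted border markers,
    expression gradients, missing coronal sections and section-to-section
    banding, so the whole screen is testable without external atlas data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
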