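Package: metastaxis
Title: Metastasis-Axis Gene Selection, Spheroid Morphometry and Variant
    Filtering for Bone-Metastasis Cell-Line Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired tumor-derived (TMD) and bone
    metastasis-derived (BMD) breast cancer cell lines.  Implements a
    principal-component-plane "metastasis axis" procedure that ranks genes
    by their loading projection onto the direction connecting the BMD and
    TMD group centroids; spheroid shape scoring (area, circularity, and a
    roughness score defined as the symmetric difference between the
    spheroid mask and its moment-fitted ellipse); quantification of
    scratch-wound closure, transwell invasion counts and microfluidic
    passing times; and classification and filtering of annotated somatic
    variants (stop-gain versus exonic missense).  Synthetic-data
    generators with retained ground truth replace the original microarray,
    image and sequencing data for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
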