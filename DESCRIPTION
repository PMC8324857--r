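Package: icnsmap
Title: Quantitative Mapping of the Intrinsic Cardiac Nervous System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for three-dimensional single-neuron maps of the
    intrinsic cardiac nervous system (ICNS). Reads and writes a documented XML
    dialect of marker/contour annotation files, filters somata by the 13 x 23
    micrometre size criterion, clusters neuron point clouds with
    partitioning-around-medoids (PAM) and selects the number of clusters by
    comparing silhouette widths against randomized-null replicates, projects
    clouds onto PCA flatmaps with Gaussian-kernel packing density, assigns
    neurons to anatomical regions of interest by contour proximity, and
    registers subjects onto a common bilinear-quad surface scaffold via
    least-squares fitting and material-coordinate embedding to quantify
    cross-subject overlap. A synthetic-heart generator with male/female
    profiles makes every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
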