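Package: intercalR
Title: Detection and Classification of Radial Cell Intercalation Events
    from 3D Nuclei Trajectories
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies radial and lateral cell intercalation
    events from 3D time-lapse trajectories of cell nuclei, as recorded in
    early zebrafish gastrulation. Cell-cell contact geometry is inferred
    from capped 3D Voronoi tessellations of nuclei positions; candidate
    intercalations are found by fitting a three-stage spatio-temporal
    template of enclosing angles and contact areas to every cell triple,
    refined by local-tissue registration and principal-axis analysis, and
    verified by displacement and directedness thresholds. Events are placed
    in an anatomical coordinate system built from a smooth surface fitted
    to the enveloping-layer nuclei, classified as upward, downward or
    lateralward, and summarised as counts, ratios, depth profiles,
    intercalation histories and spherical-harmonics directionality
    distributions. A seeded synthetic-embryo generator with planted
    ground-truth events supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
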