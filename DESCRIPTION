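Package: dropletScope
Title: Recognition, Counting and Encapsulation Statistics for Cell-Laden
    Microfluidic Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@dropletscope.org",
           role = c("aut", "cre"))
Description: Two-stage recognition of cell-encapsulated microfluidic droplets
    in brightfield micrographs. Stage one segments densely packed, adherent
    droplets as bounding circles by adaptive-scale circular template matching
    on an Otsu foreground, followed by non-maximum suppression. Stage two is a
    compact weakly supervised counting network, trained from droplet-level
    labels only (empty / single / at-least-two cells), that filters false
    proposals, counts encapsulated cells through a density map, and localizes
    each cell at the map's maxima. The package also provides the Poisson
    statistics of cell encapsulation (per-droplet cell-count distribution,
    single-cell rates, cell-per-droplet estimation) used to assess single-cell
    encapsulation performance, a seeded synthetic micrograph generator with
    full ground truth, and circle-IoU based evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
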