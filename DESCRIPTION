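Package: myxometry
Title: Image-Based Morphometry of Plasmodial Slime Mould Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image analysis of Physarum polycephalum time-lapse
    recordings: Petri-dish region-of-interest detection, adaptive-threshold
    segmentation and growth/exploration quantification, box-counting fractal
    dimension of the network, skeleton-based vein-diameter morphometry with a
    five-stage quality-control cascade, Welch power-spectral-density estimation
    of the vein contraction frequency, and estimation of total network volume
    from the 2D projection with geometric error bounds for non-circular vein
    cross-sections. A seeded phantom-image generator provides ground-truth
    fixtures so every stage can be exercised without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
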