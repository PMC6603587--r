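Package: csvdseg
Title: Patch-Based CNN Detection and Quantification of Cerebral
    Small-Vessel Lesions in 2D Brain MRI
Version: 0.1.0
Authors@R:
    person("csvdseg", "developers", email = "csvdseg@example.org",
           role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for cerebral
    small-vessel disease (CSVD) on 2D axial brain MRI slices:
    rule-based brain extraction (binarization, connected components,
    cranium removal, median filtering), tiling into 7x7 patches, a
    small 7-layer convolutional neural network (with a multilayer
    perceptron baseline) classifying each patch into non-brain, normal
    brain, central brain or lesion, reassembly into full-resolution
    label maps, lesion localization with area and diameter reporting,
    3D stacking of per-slice lesions into volume estimates, and
    rate-valued confusion-matrix evaluation (F1, precision, miss-rate
    style recall) in exact rational arithmetic. A synthetic head
    phantom generator provides paired slices and ground-truth label
    maps so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
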