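Package: breathsvm
Title: Breath VOC Blood-Glucose Classification with an Embedded-Ready RBF SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for classifying low versus high blood-glucose breath
    samples from a two-sensor volatile-organic-compound (VOC) array. Includes
    a synthetic gas-chamber simulator that emulates a timed three-chamber
    flow protocol and metal-oxide sensor dynamics for acetone and ethanol
    footprints, steady-state feature segmentation and sampling, a from-scratch
    soft-margin support vector machine with a radial basis function kernel
    trained by sequential minimal optimization, leave-one-run-out
    cross-validation over a (gamma, C) grid, and a constrained-memory
    deployment layer: packed JSON models, memory-footprint estimates, static
    C-array source emission, and a single-pass streaming classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
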