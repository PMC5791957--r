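Package: gummix
Title: Objective Masticatory Efficiency Assessment from Two-Coloured
    Chewing-Gum Mixing Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expert-system pipeline for objective assessment of masticatory
    efficiency from flatbed scans of masticated two-coloured chewing-gum
    wafers. Provides a synthetic specimen generator with ground-truth masks,
    fully automatic bolus segmentation (mean-shift filtering, a centre
    distance map, and k-means region classification), extraction of a
    121-element masticatory-performance feature vector over twelve colour
    channels (RGB, CIE-L*u*v*, HSI, normalized RGB) including the circular
    variance of hue, relevancy-based feature selection, a binary cascade of
    multilayer-perceptron classifiers gated by the Matthews correlation
    coefficient, portable XML calibration records (MEPAT), and single-test
    diagnosis reporting masticatory efficiency ME = P/T with linguistic tags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
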