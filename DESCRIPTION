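Package: vdspec
Title: Variable-Depth 3D Convolutional Networks for Hyperspectral Seed Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying seed varieties from
    hyperspectral image cubes. Reads and writes ENVI-format hypercubes,
    applies white/dark-reference radiometric correction, segments individual
    seeds from tray scenes (pseudo-RGB composite, mean filter, Otsu
    thresholding, connected components) and standardizes per-seed cubes.
    Implements a single-channel 3D convolutional network whose kernel depth
    along the spectral axis is a searched hyperparameter: an exhaustive
    odd-step depth sweep trains one model per candidate depth and selects
    the depth maximizing held-out performance. Includes a synthetic
    hyperspectral seed-scene generator for fully reproducible experiments,
    Adam optimization with softmax cross-entropy, confusion-matrix metrics,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
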