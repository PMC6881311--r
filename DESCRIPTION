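Package: canopyseg
Title: U-Net Segmentation of Vegetation Canopies in UAV Orthoimagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for fine-grained, binary semantic
    segmentation of plant canopies in very high resolution (about 3 cm
    ground sampling distance) UAV orthoimagery with a co-registered
    photogrammetric elevation model. Covers synthetic scene generation
    with texture-separable classes, raster/vector geodata handling,
    regular-grid tile sampling with train/hold-off/validation splits,
    joint image-mask geometric augmentation, a CPU U-net encoder-decoder
    trained with a dice-coefficient loss and RMSprop under an epoch
    checkpoint rule, cover-stratified accuracy and bias evaluation, and
    tile-wise map reconstruction into a georeferenced segmentation map.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
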