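Package: cropnav
Title: Crop Row Segmentation and Navigation Line Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Vision pipeline for agricultural machinery guidance: a lightweight
    encoder-decoder semantic segmentation network (MobileNetV2-style backbone with
    split-attention bottlenecks, a densely connected atrous spatial pyramid with strip
    pooling, and a convolutional block attention decoder) that labels crop-row pixels in
    RGB field images, together with the geometric post-processing that turns binary row
    masks into per-row navigation lines (density-based row-instance clustering, moment
    anchor extraction with gap repair, and RANSAC line fitting). Includes a seeded
    synthetic field-scene generator, combined focal + dice training loss, a
    confusion-matrix metric suite, and navigation-line error measures, so every stage is
    testable without field imagery. The network runs on a small self-contained
    tensor/autodiff engine with C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    EBImage,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
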