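Package: ivusseg
Title: Automatic Lumen and EEM Segmentation of Coronary IVUS Frames with a Deep U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic semantic segmentation of short-axis intravascular
    ultrasound (IVUS) frames into background, lumen and the external elastic
    membrane (EEM) ring, using a deep encoder-decoder convolutional network
    with eight stride-2 downsamplings. Includes coordinate-channel (MeshGrid)
    and flip/rotate online data augmentation, sparse softmax cross-entropy
    training with a step learning-rate schedule and Adam, mean
    intersection-over-union (MIoU) evaluation, an ablation harness over
    augmentation strategies, a synthetic IVUS phantom generator for fully
    self-contained testing, and readers/writers for multi-frame DICOM, PNG
    masks and dataset manifests. The network, its gradients and the optimiser
    are implemented in the package itself with BLAS-backed im2col/GEMM
    convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
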