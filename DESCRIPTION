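Package: cfsgunet
Title: Rib Fracture Detection in Chest CT with a Dual-Attention 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Segmentation-based detection of rib fractures in chest computed
    tomography. Implements the CFSG U-Net: a residual 3D encoder-decoder
    whose skip connections are refined by a channel-wise fusion attention
    module (CFAM) and whose decoder features are refined by a spatial-wise
    group attention module (SGAM). Includes morphological bone-region
    extraction from Hounsfield-unit volumes, a Dice plus weighted binary
    cross-entropy training objective, balanced patch sampling with
    augmentation, sliding-window whole-scan inference with
    connected-component proposal extraction, FROC evaluation at fixed false
    positives per scan, and a synthetic thorax phantom generator so the
    whole pipeline is exercisable without clinical data. The network
    forward and backward passes are implemented natively (Rcpp kernels and
    a small reverse-mode tape).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
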