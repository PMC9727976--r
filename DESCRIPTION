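Package: fundusseg
Title: Joint Optic Disc and Cup Segmentation for Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint segmentation of the optic disc and optic cup in
    retinal fundus photographs, aimed at cup-to-disc ratio estimation for
    glaucoma screening. Provides multi-scale Retinex colour-restoration
    (MSRCR) enhancement, pixel-wise polar warping about the disc centre and
    its exact inverse, a residual spatial-attention U-shaped segmentation
    network (RSAP-Net) with a multi-branch dilated-convolution and global
    information coding bottleneck, trained with three-class cross-entropy and
    stochastic gradient descent, plus a full evaluation suite (F1, accuracy,
    specificity, sensitivity, radial boundary localization error and vertical
    cup-to-disc ratio) and a synthetic fundus generator for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
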