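Package: latatk
Title: Lesion-Area-Constrained Adversarial Attacks on Medical Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates adversarial perturbations for medical image
    classifiers that are confined to a segmented lesion region. A trained
    encoder-decoder generator emits a Tanh-bounded perturbation field that
    is epsilon-scaled, restricted to a binary lesion mask and clipped to an
    epsilon-ball around the original image. Generator training maximises
    classifier cross-entropy and a Grad-CAM class-activation discrepancy
    (for transferability) while minimising a local-binary-pattern texture
    discrepancy (for concealment). Includes a U-Net style lesion segmenter,
    small convolutional classifiers, a synthetic dermoscopy-like fixture
    generator, and evaluation by attack success rate and the structural
    similarity index (SSIM). All networks and their training loops are
    implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    png,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
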