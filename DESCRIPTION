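Package: sinoseg
Title: Sinogram-Domain Breast Lesion Segmentation and Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction-free localization of breast lesions directly in the
    sinogram domain. Generates seeded synthetic mammography and digital breast
    tomosynthesis (DBT) phantoms with annotated masses, maps images and masks to
    sinograms with a parallel-beam Radon transform under a limited-angle
    (+/-25 degrees, 2.5 degree step) geometry, segments lesion traces with a
    U-Net encoder-decoder trained under a hybrid binary cross-entropy + Dice
    objective, verifies localization by filtered backprojection of predicted
    sinogram masks, and quantifies it with centroid-distance,
    diagonal-normalized overlap and lesion-cropped IoU metrics. The network,
    Radon transform and filtered backprojection are implemented in compiled
    code; all results are tabulated as tibbles with tidy(), glance() and
    autoplot() support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
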