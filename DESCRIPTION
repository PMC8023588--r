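Package: octsubset
Title: Annotation-Efficient Training-Image Selection for Intravascular
    OCT Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reducing the annotation burden of slice-wise
    semantic segmentation of intravascular optical coherence tomography
    (IVOCT) pullbacks. Implements polar-domain preprocessing (guidewire
    shadow zeroing, lumen pixel-shift alignment, depth cropping, log
    transform and Gaussian speckle reduction), two training-frame subset
    selectors (equal z-spacing and deep-feature clustering via a
    convolutional autoencoder, PCA and k-medoids), a compact U-net
    segmentation stage trained with weighted binary cross-entropy and
    early stopping, pixel-level evaluation (per-class F1, average
    precision with normal-volume exclusion, Bland-Altman agreement on
    clinical calcification attributes), and the full multi-model
    comparison protocol. A synthetic polar phantom generator with ground
    truth makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
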