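Package: fundusadapt
Title: Unsupervised Domain Adaptation for Optic Disc and Cup Segmentation in Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint optic-disc and optic-cup segmentation with unsupervised
    domain adaptation for glaucoma screening. A convolutional autoencoder
    enhances the labeled source domain, a boundary-aware segmentation
    network (encoder with atrous spatial pyramid pooling, a boundary
    regression branch and a boundary-conditioned mask branch) is trained
    adversarially against three patch discriminators that align boundary
    and mask predictions across domains, and a clinical evaluation stack
    computes Dice overlap, vertical cup-to-disc ratio and its error,
    ROC/AUC for screening, and weighted-rank challenge scores. Includes a
    seeded synthetic fundus generator with a controllable source-to-target
    domain shift so the whole pipeline runs at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
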