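Package: retinaseg
Title: Reconstruction-Based Pre-Training and Hybrid CNN-Transformer
    Segmentation for Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised reconstruction pre-training of a hybrid
    convolutional-transformer encoder-decoder (TransUNet-style) on unlabeled
    2D electron-microscopy patches, selective transfer and freezing of the
    transformer parameters for fine-tuning on labeled data, slice-wise and
    orthoplane volumetric inference, and semantic-segmentation evaluation
    (IoU, precision, recall, F-score, Mean False Distance, CREMI-style
    ADGT/ADF).  Includes a synthetic EM-like image and volume generator so
    the full pipeline is testable at desk scale, paired data augmentation
    with exact geometric target alignment, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
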