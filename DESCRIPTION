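Package: hsderm
Title: Hyperspectral Dermatology Image Analysis for Pigmented Skin Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of snapshot visible/near-infrared hyperspectral
    images of pigmented skin lesions: ENVI cube input/output, radiometric
    calibration against white and dark references, band trimming, spectral
    smoothing and per-signature normalization, spectral-angle-mapper (SAM)
    assisted labeling, unsupervised lesion segmentation combining K-means with
    a five-signature reference spectral library, supervised pixel
    classification (support vector machines, random forest, feed-forward
    neural network) with genetic-algorithm hyperparameter tuning, overlap and
    ROC evaluation metrics, and a lesion-level malignancy decision based on a
    malignant-pixel risk threshold. Includes a seeded synthetic scene
    generator that emulates the acquisition geometry (50 x 50 pixels, 125
    bands over 450-950 nm) with known ground truth, so every stage of the
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    cluster,
    e1071,
    kernlab,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
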