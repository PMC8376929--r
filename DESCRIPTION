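Package: kneepipe
Title: Automated Grading of Knee Osteoarthritis Features from Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for automated assessment of knee osteoarthritis severity
    on plain radiographs. Provides radiograph preprocessing (polarity
    normalization, double-knee splitting, histogram equalization), a two-stage
    cascaded multi-task convolutional detector that localizes the knee joint and
    six anatomical key points via an image pyramid with non-maximum suppression,
    key-point-driven region-of-interest refinement with symmetric patch
    splitting, and a Siamese squeeze-and-excitation ResNext grading network with
    adaptive gated feature fusion that jointly predicts the Kellgren-Lawrence
    grade, six OARSI feature grades (joint space narrowing and osteophytes per
    compartment) and a binary osteoarthritis label. Includes a deterministic
    synthetic knee-phantom generator with exact ground truth, CPU-scale training
    utilities, and ordinal evaluation metrics (top1, top+/-1 accuracy, weighted
    Cohen's kappa, mean squared error, confusion matrices). The network engine
    (grouped convolutions, pooling, backpropagation, Adam) is implemented in
    'Rcpp'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
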