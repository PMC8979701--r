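Package: accnet
Title: Augmentation-Consistent Clustering Networks for Semi-Supervised Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised training of image classifiers from a small labeled
    set and a larger unlabeled pool, aimed at screening tasks such as binary
    normal/abnormal grading of retinal fundus photographs. Combines
    weak/strong augmentation consistency (random crop/flip anchors versus
    RandAugment-plus-cutout views) with a soft-weighted clustering
    pseudo-labeller: class centroids are estimated from softmax-weighted
    features, smoothed through a dynamically updated global centroid memory
    with damped rate exp(-t_k), and pseudo-labels are assigned by
    nearest-centroid matching. Training minimises a four-term objective
    (labeled cross-entropy, augmentation consistency, local/global centroid
    consistency, pseudo-label cross-entropy). Includes a class-conditional
    synthetic image generator, a compact CNN backbone with exact backprop
    (conv kernels in compiled code), evaluation metrics
    (accuracy/sensitivity/specificity/AUC, ROC, confusion matrices), an
    ablation harness, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
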