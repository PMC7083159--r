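Package: crmens
Title: Class-Selective Relevance Mapping and Ensemble Localization for
    CNN Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining and evaluating convolutional neural
    network (CNN) classifiers of chest radiographs. Implements the
    class-selective relevance mapping (CRM) saliency score, which measures
    the summed squared change in all output-node scores when a spatial
    element of the deepest convolutional feature maps is removed, both by
    brute-force removal and by an exact closed form for global-average-
    pooling linear heads. Fuses relevance maps from several models into an
    ensemble heatmap (upscale, threshold at a fraction of each map's
    maximum, average, display-threshold), turns heatmaps into bounding-box
    detections, and scores them against ground truth with IoU,
    precision-recall curves, average precision and mAP over a range of IoU
    thresholds. Also provides softmax-probability ensembling (majority
    voting, simple and weighted averaging, stacking with a small neural
    meta-learner), a classification metric suite (accuracy, AUC,
    sensitivity, specificity, F measure, Matthews correlation coefficient)
    with Wilson score intervals, lung-mask-driven preprocessing, a
    seed-reproducible synthetic chest-image generator with known lesion
    boxes, and a factory for tiny trainable separable-convolution CNNs so
    the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
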