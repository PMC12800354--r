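Package: iccaWSI
Title: Weakly Supervised Prediction of iCCA Transcriptomic Classes from
    Whole-Slide Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for predicting the five transcriptomic
    classes of intrahepatic cholangiocarcinoma (iCCA) from whole-slide
    histology images. Provides Otsu tissue detection and non-overlapping
    tessellation with three region-of-interest protocols (no filter, tumour
    mask filter, learned tile filter); deterministic tile featurization and
    view-ensembled, L2-normalized slide embeddings; a gated attention-based
    multiple-instance-learning baseline trained from scratch; L2-regularised
    logistic classification heads with patient-level stratified
    cross-validation and fold-ensembled external inference; an RNA-side
    gene-signature classifier (gene filtering, quantile normalization,
    gene-wise centring, signature-mean scoring); cohort statistics
    (chi-squared, Fisher exact, Student t, Kaplan-Meier, log-rank); and a
    fully synthetic multi-modal cohort generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    limma,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
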