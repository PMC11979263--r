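Package: stenomics
Title: Segmentation-Free Coronary Stenosis Grading from Straightened Vessel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient-level grading of coronary artery disease severity from
    straightened (multiplanar-reconstruction style) CCTA vessel images without
    lesion segmentation. The package extracts 465 two-dimensional radiomic
    features (first-order statistics plus five gray-level texture-matrix
    families, computed on the original image and four single-level wavelet
    bands) and a learned latent representation from a dense autoencoder,
    fuses the two feature domains, filters them with a Spearman-redundancy /
    rank-sum / LASSO selection chain, and classifies each image with a
    two-stage random-forest cascade (no CAD vs. CAD, then nonobstructive vs.
    obstructive) aggregated per patient by majority voting. A seeded
    synthetic-cohort generator emulates the statistical structure of
    straightened-vessel image sets with known stenosis ground truth, and
    evaluation utilities provide patient-stratified splits, macro-averaged
    metrics and clinical-association testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    igraph,
    jsonlite,
    pROC,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
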