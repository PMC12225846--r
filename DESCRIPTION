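Package: glottisQC
Title: Reference-Free Segmentation Quality Prediction for Laryngeal Endoscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the quality of glottal-area segmentation
    masks in laryngeal endoscopy without ground truth. Implements a stochastic
    mask-corruption pipeline (uniform morphological scaling, Sobel border
    fuzz, small disc artifacts, Perlin-noise blobs) that labels degraded masks
    with their exact intersection-over-union (IoU), IoU-balanced regression
    dataset construction, a convolutional IoU regressor over configurable
    image/mask channel schemes, inter- and intra-rater reliability analysis
    (IeRR/IaRR) with area- and distance-stratified breakdowns, and a
    traffic-light per-frame quality report for endoscopy videos. Synthetic
    glottis phantoms make every component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, Segmentation, QualityControl, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'artifact-generator.R'
    'config-io.R'
    'iou-metrics.R'
    'dataset-builder.R'
    'fixtures.R'
    'perlin.R'
    'regressor.R'
    'reliability.R'
    'traffic-light.R'
    'zzz.R'
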