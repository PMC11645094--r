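Package: fatlat
Title: Latent-Space Assessment of Exercise-Induced Fatigue from Wearable
    Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing neuromuscular fatigue from multimodal
    wearable-sensor recordings of repeated exercise. Provides a synthetic
    cohort generator (balance-board forces and inertial measurement units
    with parametric fatigue drift), a preprocessing pipeline producing
    fixed-length standardized repetition matrices, semi-supervised and
    conditional adversarial autoencoders that embed repetitions into a
    two-dimensional latent space regularized to per-activity Gaussian
    modes, cluster-drift indices (silhouette, Davies-Bouldin, 95 percent
    confidence-ellipse area, centroid distance) computed per set of
    repetitions, and completion-normalized linear-regression summaries
    that count significant fatigue trends across cross-validation folds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    data.table,
    signal,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
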