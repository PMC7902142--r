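Package: gaitanomaly
Title: Online Gait Anomaly Detection from Binary Silhouette Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online detection of abnormal walking patterns from ordered
    binary silhouette image sequences. Builds per-subject gait energy
    images (GEI), maintains an incrementally updated population-level
    full gait energy image (F-GEI), extracts a two-dimensional deviation
    feature (mean and standard deviation of per-frame overlap with the
    thresholded high-energy region), and classifies each passing subject
    as normal or abnormal with a boundary-clamping constrained K-means
    (BC-COP-K-means) that needs only a handful of pre-labeled subjects.
    Includes a parametric synthetic silhouette walker for fully
    reproducible cohorts, silhouette preprocessing (morphological
    denoising, largest-component extraction, size normalization and
    centroid alignment), and evaluation by correct classification rate
    over all subjects and over abnormal subjects only.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
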