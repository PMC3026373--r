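Package: lesionborder
Title: Lesion Border Extraction from Dermoscopy Images by Density-Based
    and Fuzzy C-Means Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated extraction of pigmented skin lesion borders from
    dermoscopy images with two interchangeable clustering back-ends: a
    grid-adapted density-based clusterer (DBSCAN) operating on binarized
    images, and a fuzzy c-means segmenter with membership-threshold
    defuzzification. Includes construction of dermatologist-style ground
    truth masks from border control points via a closed quadratic B-spline,
    the standard segmentation evaluation metrics (XOR border error,
    precision, recall) with per-image batch reports, and a synthetic
    dermoscopy-like lesion generator with exact ground truth for testing
    the full pipeline without clinical images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jpeg,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
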