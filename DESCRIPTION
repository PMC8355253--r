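Package: wsicascade
Title: Coarse-to-Fine Cascaded Segmentation of Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for efficient pixel-level lesion segmentation of very large
    whole-slide images (WSIs) using a cascaded, multi-level tile pyramid.
    A slide is decomposed into non-overlapping fixed-size tiles at several
    resolution levels; a per-level segmentation model scores every coarse tile,
    a binary attention map gates which tiles are inspected at each finer level,
    and the final lesion mask is assembled from the selected full-resolution
    tiles only.  Includes the spatial-dimension trace of a single-stream
    FCN-32s tile segmenter and a trainable reduced-width variant with seeded
    stochastic gradient descent, closed-form threshold segmenters for exact
    cascade/dense equivalence checks, pixel-level evaluation metrics
    (precision, recall, F-measure, Jaccard, specificity) with explicit
    degenerate-case conventions, per-slide aggregation, Fisher's least
    significant difference pairwise comparisons, throughput projection
    arithmetic, and a seeded synthetic-slide generator that produces sparse
    elliptical lesions with exact ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
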