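Package: leafsrc
Title: Discriminant Weighted Sparse Representation Classification of Leaf Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage sparse-representation classification of plant leaf
    images. Training contours are partitioned into shape-similar groups by
    Gaussian-kernel similarity to representative "typical" leaves; a test
    leaf is routed to the most similar group and classified by a weighted
    l1-regularized reconstruction on that group's subdictionary, the label
    being the species with the smallest size-normalized residual. Includes
    the full contour preprocessing chain (grayscale conversion, background
    removal, median denoising, petiole removal, principal-axis alignment,
    edge extraction, 32x32 normalization), unweighted and weighted sparse
    classifier baselines, an evaluation harness, and a deterministic
    synthetic leaf-shape generator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
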