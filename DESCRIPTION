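Package: countseg
Title: Fast Exact Segmentation of Count Data by Pruned Dynamic Programming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact multiple change-point detection for one-dimensional count
    series such as RNA-seq or DNA-seq per-base coverage. Implements the
    pruned dynamic programming (functional pruning) algorithm for convex
    one-parameter losses (negative binomial, Poisson, Gaussian), lossless
    plateau compression of the signal, a sliding-window median moment
    estimator of the negative binomial overdispersion, penalized model
    selection of the number of segments with an oracle penalty calibrated
    by the slope heuristic, constrained-breakpoint segmentation queries,
    and segmentation-quality metrics (a non-adjacent-pair Rand index and
    Hellinger-distance profile comparison). Includes a seeded simulator of
    piecewise-constant negative binomial profiles and a command-line
    interface for shell pipelines.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
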