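Package: chromalign
Title: Multiple Retention-Time Alignment of GC-MS Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiple retention-time alignment for GC-MS chromatograms.
    Implements peak-based multiple alignment by bidirectional best-hit
    assignment and greedy clique extension over a K-partite peak similarity
    graph, profile alignment by center-star multiple alignment with
    anchor-partitioned dynamic time warping (row-compressed banded dynamic
    programming with Sakoe-Chiba constraints), a hybrid mode in which peak
    cliques constrain the warping search space, a precision/recall evaluation
    harness against ground-truth peak groups, and a seeded synthetic
    chromatogram generator with controllable retention-time warp, intensity
    noise, and peak dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    mzR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
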