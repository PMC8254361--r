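Package: spathet
Title: Spatial Heterogeneity Scoring for Single-Cell Copy-Number Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies spatial intra-tumor heterogeneity from single-cell
    copy-number (scCNA) matrices produced by third-party callers. Computes a
    silhouette-style Spatial Heterogeneity score (SHscore) over multi-regional
    tumor samples using Manhattan (L1) distances between per-cell copy-number
    profiles, scans all sample partitions to find the most divergent grouping,
    and provides readers for common caller output formats, cell filtering by
    ploidy and median absolute deviation, feature selection, dimensionality
    reduction, clustering wrappers, and a beta-splitting cell-division tree
    simulator with copy-number event accrual for validating the score under
    controlled tumor-evolution scenarios.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    mclust,
    kernlab,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    uwot,
    pheatmap,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
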