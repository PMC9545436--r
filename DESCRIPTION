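Package: gfzone
Title: Gradient Forest Landscape Genomics and Seed Zone Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-SNP regression forests against climate predictors and
    aggregates split importances into density-standardized cumulative-importance
    (turnover) functions, transforms climate grids into multidimensional
    genomic-composition surfaces, summarizes them by principal components, and
    delineates seed and breeding zones by partitioning-around-medoids clustering
    with within-cluster-variation scans, zone-area accounting and overlap
    validation against reference delineations. Includes a synthetic-landscape
    generator (Gaussian-random-field climate grids, logistic allele-frequency
    clines, Balding-Nichols neutral structure) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
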