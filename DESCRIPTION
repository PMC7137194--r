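Package: degor
Title: Differential Expression by Quantile-Difference Outlier Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes between two experimental
    conditions by representing each gene as a vector of quantile differences,
    scoring genes with a distance-based outlier ratio (OR) against a
    permutation null, measuring false-positive contamination of each
    candidate's K-nearest neighbourhood (FP and its inverse-distance density
    dFP) with fold-partitioned null cases, applying strong and relaxed
    selection rules, and clustering candidates with partitioning around
    medoids under silhouette-based model selection. Includes a synthetic-study
    generator with known ground truth, detection scoring, ggplot2 graphics,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
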