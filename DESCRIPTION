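Package: altex
Title: Co-Occurrence and Mutual Exclusivity Tests for Somatic Alterations
    with Tumor-Specific Alteration Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests for co-occurrence and mutual exclusivity of
    somatic alterations in tumor cohorts that do not assume identically
    distributed alterations across tumors. A per-gene, per-tumor background
    alteration probability matrix is estimated by margin-constrained entropy
    maximization, pairwise and groupwise alteration overlaps are tested
    against Poisson-binomial null distributions, and multiple testing is
    corrected with a step-up false discovery rate procedure adapted to
    discrete test statistics. Includes a degree-preserving simulation
    framework for benchmarking calibration and sensitivity, and de novo
    detection of mutually exclusive gene sets by weighted overlapping
    correlation clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
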