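Package: adelle
Title: Global Trans-eQTL Testing by Aggregating Dependent Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Global tests of the null hypothesis that a SNP is associated
    with none of its trans gene-expression traits, built from per-trait
    association summary statistics (Z scores or p-values with signs).
    Implements the equal-local-levels (ELL) order-statistic test for
    independent traits with exact global/local level calibration, and its
    extension to dependent traits via a moment-matched beta-binomial
    approximation to the correlated exceedance count, with Monte Carlo
    p-value calibration under a shrinkage-regularised trait correlation
    matrix. Includes the standard competitor tests (Bonferroni Min-P,
    Simes, Cauchy combination, sum of chi-squares, CPMA, and an
    independence-l-value variant), a per-SNP genome scan with
    Benjamini-Hochberg discovery, and a simulation harness for type-1
    error and power studies in the rare-weak signal regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    pracma,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
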