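Package: ritss
Title: Robust Interaction Testing Using Sample Splitting for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for gene-environment interaction in quantitative traits by
    screening for aggregated interaction scores (weighted sums of
    variant-by-exposure product terms) in one part of the data and testing them
    in a disjoint part with an orthogonalized, misspecification-robust product
    statistic combined across K cross-fitting folds. Includes two screening
    strategies (approximate best-subset selection of genetic risk score
    subcomponents, and FDR-based aggregation of single-variant interaction
    scans), single-variant spline-based comparator tests, non-robust variants
    of the main statistic, a simulation module generating null and power
    scenarios for type-1-error and power studies, and a validation regression
    with heteroscedasticity-consistent standard errors for independent
    replication data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    sandwich,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
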