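Package: csme
Title: Cell-Subtype Specific Methylation Estimation from Mixed-Cell Beta Values
Version: 0.1.0
Authors@R:
    person("Methylation", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates per-CpG simple linear regression for estimating
    cell-subtype specific DNA methylation differences from mixed-cell
    (whole blood) beta values and measured cell-type proportions. Provides
    a seeded synthetic-data generator emulating paired cell-sorted and
    whole-blood 450K-style designs, candidate CpG panel selection by pooled
    t-tests with Benjamini-Hochberg FDR control, calibration of regression
    estimates against cell-sorted references, a standardized discrepancy
    (D) screen with a Student-t reference distribution, and Table-style
    performance reports (MAE, MMCE, R-squared), panel overlap validation
    and hierarchical clustering of sorted samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
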