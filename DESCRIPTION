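Package: sexdiffr
Title: Multi-Cohort Meta-Analysis of Molecular Sex Differences in Serum
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting reproducible molecular sex differences
    across independent cohorts of serum analyte panels. Implements the
    full analysis pipeline: covariate-based male-female matching,
    replacement of out-of-range immunoassay values, missingness and
    outlier filtering, per-cohort Cliff's delta effect sizes with
    consistent variance estimates, DerSimonian-Laird random-effects
    pooling with chi-squared heterogeneity tests and Benjamini-Hochberg
    false discovery rate control, k-means clustering of analytes on a
    reference cohort, sign-oriented first-principal-component composite
    variables per cluster, and sex-by-condition interaction testing
    against a disease cohort. Ships a synthetic multi-cohort study
    generator with ground truth so every stage is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
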