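Package: drmvalidate
Title: Scoring and Test-Retest Validation of the Abbreviated Day
    Reconstruction Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring episode-level affect data collected with the
    abbreviated Day Reconstruction Method (DRM) and for running the full
    test-retest and criterion-validity analysis battery used to validate
    short DRM forms against the original full-day instrument.  Provides
    duration-weighted positive/negative/net affect and U-index scoring with
    set-specific rules, one-way intraclass correlation with F-based
    confidence intervals, Dunlap-corrected paired-sample effect sizes,
    Cohen's and weighted kappa, the Delta chance-corrected agreement
    coefficient for two-category items, a nonparametric ROC-type area under
    the curve for continuous gold standards, interaction regression of net
    affect on demographics with nested-model tests, per-activity affect
    profiling with ranking-stability statistics, and a synthetic cohort
    generator with known ground truth so every statistic can be verified by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
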