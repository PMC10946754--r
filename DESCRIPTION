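Package: itsagree
Title: Agreement of Interrupted Time Series Effects Estimated from Digitized Graph Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether interruption effect estimates computed
    from digitally extracted interrupted time series (ITS) graph data agree
    with estimates computed from the original data. Provides a synthetic
    cohort generator that simulates segmented-regression series with lag-1
    autocorrelated errors together with realistic digitization error
    processes (constant time offsets, time-scale drift, outcome jitter,
    missing points, collided time points); readers for digitizer-exported
    x/y point files with grid snapping and duplicate/missing handling;
    segmented linear regression by OLS and by REML with stationary AR(1)
    errors, including a group-level OLS fallback policy; calibration
    regressions quantifying extraction error with an important-error rule;
    and agreement analyses (Bland-Altman limits of agreement, geometric-mean
    standard error ratios, scaled confidence interval comparisons, p-value
    category concordance) across data sources.
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
    nlme,
    optparse
Config/testthat/edition: 3
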