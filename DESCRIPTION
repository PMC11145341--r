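Package: percept
Title: P-Value-Weighted Scaling of Effect Sizes for Small-Sample Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Replaces binary p-value thresholding with a continuous
    transform that scales each measured effect toward a hypothetical mean
    with an intensity governed by its p-value: V = m0 + (m1 - m0) * F^(-p),
    where F is a tunable penalty factor. Includes per-feature application
    to abundance tables via one-sample t-tests, data-driven effect-size
    thresholds from pseudo-control randomization, volcano-plot
    categorization, a replicate-image demonstration comparing mean
    smoothing against p-value scaling, small-sample subsampling evaluation
    with distance-to-population and interpolated cumulative distributions,
    Bland-Altman agreement, cross-dataset correlation, and seeded synthetic
    data generators so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
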