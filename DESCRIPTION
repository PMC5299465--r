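Package: iccpower
Title: Repeatability of High-Throughput Assays and Sample-Size Inflation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes the technical precision of multiplex
    (high-throughput) assays from technical-replicate pilot data and feeds
    that information into study design. Fits the one-way random-effects
    variance-components model per analyte by closed-form ANOVA, estimates
    repeatability (the intraclass correlation coefficient) with parametric
    bootstrap confidence intervals, quantifies why the inter-replicate
    sample correlation r is a misleading precision measure (it is confounded
    with dynamic-range variance), and plans sample sizes via the sample size
    inflation factor (SIF): an analyte is powered when SIF exceeds 1/R.
    Includes a synthetic-data generator for the hierarchical Gaussian model,
    publication-style diagnostics, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    ggplot2,
    jsonlite,
    patchwork,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
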