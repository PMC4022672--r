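Package: cvdelta
Title: Differential Gene-Expression Variability Between Knockout and
    Wild-Type Replicate Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares the variability (coefficient of variation, CV) of gene
    expression between two groups of biological replicates, probe set by
    probe set, on Affymetrix-style expression matrices. Implements the
    per-probe-set delta-log10-CV statistic, median-expression filtering,
    a one-sample two-tailed t-test computed in log space so that p-values
    far below double-precision underflow remain representable, and
    distributional diagnostics that discriminate outlier-driven from
    global variability shifts (bootstrap confidence intervals for
    mean minus median). Includes a reader for GEO Series Matrix files, a
    synthetic expression-matrix generator with a known variability
    fold-change for ground-truth validation, and multi-dataset collection
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
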