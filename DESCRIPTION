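Package: nlaconn
Title: Network-Level Analysis of Parcellated Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and localizes covariate-related differences in
    parcellated functional connectomes. Fits edgewise marginal models
    with cluster-robust (Huber-White) standard errors and wild cluster
    bootstrap null distributions, performs network-level enrichment
    inference (Welch's t against the whole connectome) with
    Westfall-Young step-down family-wise error control, compares
    parcellated cortical maps with rotational spin-test nulls, and
    provides the accompanying power analysis for network-level tests.
    Includes a synthetic-cohort generator (parcellations, clustered
    cohorts, connectivity matrices, BOLD-like time series) so the whole
    pipeline can be exercised and calibrated without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
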