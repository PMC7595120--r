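Package: ctdsnet
Title: Controlled Time Delay Stability Networks for Multichannel Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers directed coupling networks from multichannel, uniformly
    sampled time series using Time Delay Stability (TDS) and its controlled
    extension (CTDS), in which each pairwise link is estimated with an
    Nth-order partial cross-correlation that adjusts for all remaining
    channels. Includes segment-wise lagged (partial) cross-correlation, the
    four-of-five-consecutive-segments stability rule and percentage-of-time
    link strength, vector-autoregressive network simulators with known ground
    truth, cross-subject surrogate significance testing with threshold
    selection, consensus-network construction, and rank-based and correlation
    summaries for benchmarking link recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
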