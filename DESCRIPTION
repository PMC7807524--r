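Package: livertrack
Title: Latency-Compensated Liver Motion Tracking from Chest-Surface Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Indirect real-time tracking of internal liver motion from external
    chest-surface breathing signals, as used in surface-guided radiation
    therapy. Provides a peephole long short-term memory (LSTM) network and an
    epsilon-insensitive support vector regression (SVR) model for two tasks:
    forward prediction of the external surrogate signal to compensate system
    latency, and regression of internal liver displacement from external
    windows. The two stages compose into an integrated tracker that predicts
    internal position ahead of real time. Also includes a seeded synthetic
    generator of paired surface/liver breathing traces, signal preprocessing
    (resampling, Hampel outlier replacement, smoothing, zero-phase low-pass
    filtering, standardization), RMSE/MAE/maximum-error reporting, and a
    cumulative model-update study protocol for quantifying the benefit of
    refreshing the external/internal correlation model over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    kernlab,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
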