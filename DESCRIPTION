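Package: narxgait
Title: Myoelectric NARX Prediction of Future Ankle Angle and Moment
Version: 0.1.0
Authors@R:
    person("narxgait", "developers", email = "narxgait@example.org",
           role = c("aut", "cre"))
Description: Tools for continuous, simultaneous prediction of future ankle
    angle and ankle moment from surface electromyography (EMG) linear
    envelopes with a multiple-input multiple-output feedforward (open-loop)
    nonlinear autoregressive network with exogenous inputs (NARX). Includes
    the full signal-conditioning chain (zero-phase Butterworth EMG envelope,
    kinetic and kinematic filtering, trial truncation), Levenberg-Marquardt
    training with trial-blocked cross-validation and multi-restart selection,
    hyperparameter characterization over prediction interval, sampling
    window and hidden-layer size, performance evaluation (RMSE,
    cross-correlation peak R-squared, instantaneous RMSE, constant-EMG
    ablation, gait critical-point statistics with Benjamini-Hochberg
    correction), and a seeded synthetic multi-condition gait generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
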