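Package: pulseguard
Title: Cuffless Blood Pressure Estimation and Anomaly Detection for Wearable Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates arterial blood pressure from photoplethysmogram (PPG) and
    electrocardiogram (ECG) signals without a cuff. Provides a seeded synthetic
    cardiovascular signal simulator with per-beat systolic/diastolic ground truth,
    five neural sequence-regression architectures (fully connected, LSTM, WaveNet,
    WaveNet-LSTM, ResNet-LSTM) with direct SBP/DBP, entire-waveform and
    hypertension-stage heads trained by a built-in gradient engine, leave-one-out
    subject evaluation with MAE/RMSE reporting, analytic FLOPs cost estimation, a
    model-of-normality anomaly detector with six working-point threshold rules, and
    heart-rate zone analytics for wearable CSV exports. A single command-line entry
    point wires all stages into reproducible, seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
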