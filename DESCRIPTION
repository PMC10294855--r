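Package: hranomaly
Title: Unsupervised Anomaly Detection in Nocturnal Heart-Rate Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting anomalous heart-rate values in nightly
    wearable-device recordings. Provides a seeded synthetic generator for
    nocturnal beats-per-minute series with known injected anomalies, an
    ensemble auto-labeling rule (isolation forest, one-class SVM and kernel
    density estimation intersected, then unioned with a tumbling-window
    three-sigma rule), forecasting-based detectors (ARIMA, stacked LSTM,
    convolutional-autoencoder LSTM, BiLSTM and a beta-VAE with BiLSTM
    encoder/decoder whose latent embeddings are forecast by a BiLSTM
    module), threshold tuning on a validation night, and raw plus
    segment-adjusted precision/recall/F1 evaluation with a t-SNE map of the
    latent space. Neural components are implemented natively on a small
    reverse-mode automatic-differentiation core.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, e1071, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
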