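Package: emochart
Title: Emotion Charting from Multimodal Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline for classifying emotional states in the
    valence-arousal plane (HVHA, HVLA, LVHA, LVLA) from multimodal
    physiological recordings (14-channel EEG, 2-channel ECG, 1-channel GSR).
    Recordings are segmented into overlapping 30 s windows, bandpass
    filtered per modality, EEG is unmixed with fixed-point independent
    component analysis, each channel is converted to a discrete-wavelet
    scalogram image, a contractive stacked convolutional autoencoder learns
    compressed bottleneck features, and an ensemble of a linear one-vs-rest
    SVM, a random forest and an LSTM classifies the four quadrants by
    majority vote. Includes EDF and MATLAB-container readers and writers, a
    synthetic multimodal recording generator with class-dependent spectral
    and autonomic signatures, k-fold evaluation with one-vs-all
    sensitivity/specificity, and an ablation harness over the
    preprocessing/feature/classifier ladder.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
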