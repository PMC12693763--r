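Package: ecgmtl
Title: Multi-Task ECG Denoising, Quality Assessment and Noise Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-lead ECG signal quality work built around a
    multi-task conv+Transformer encoder-decoder that jointly denoises a 5 s
    (1000-sample, 200 Hz) ECG window, estimates a per-sample noise-level
    graph, and classifies three-level signal quality (Good/Medium/Bad).
    Includes SNR-controlled synthesis of noisy ECG from clean templates with
    baseline-wander, electrode-motion and muscle-artifact noise models; weak
    per-R-R-interval noise labels from local SNR and correlation; a classical
    preprocessing chain (median-filter baseline removal, 1-40 Hz band-pass,
    Savitzky-Golay smoothing, Pan-Tompkins R-peak detection, db6 wavelet
    delineation); eleven handcrafted signal-quality indices with a one-class
    SVM clean-segment selector; task losses combined by learned homoscedastic
    uncertainty; and model compression by structured pruning plus 8-bit
    weight quantization. The network, its backpropagation and the Adam
    optimizer are implemented directly on matrix operations so the full
    pipeline runs without a deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
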