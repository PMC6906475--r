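Package: spikespeech
Title: Speech Reconstruction from Intracortical Multiunit Spiking Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for decoding audio from multielectrode
    intracortical recordings of auditory cortex. Converts broadband voltage
    traces into binned multiunit threshold-crossing features, regresses
    mel-spectrogram audio targets on those features with seven decoder
    families (Kalman filter, Wiener filter, Wiener cascade, and dense,
    simple-recurrent, GRU and LSTM neural networks), reconstructs waveforms
    by mel inversion and Griffin-Lim phase recovery, and scores
    reconstructions with six quality metrics (mel-band correlation, envelope
    correlation, gross pitch error, loudness factor, ESTOI and STMI)
    together with the matching statistical comparison framework. Includes a
    synthetic session generator (word-like tokens driving spectrotemporally
    tuned Poisson spiking) so the full pipeline is testable without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
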