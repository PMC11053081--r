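Package: ecogspeech
Title: Closed-Loop Synthesis of Speech from Electrocorticographic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trainable, testable re-implementation of an online
    electrocorticography (ECoG) to speech synthesis pipeline for
    brain-computer interfaces. Provides causal broadband high-gamma
    feature extraction (per-grid common-average referencing, order-8
    Butterworth band-pass/band-stop filtering, 50 ms/10 ms log-power
    frames, day-specific baseline normalisation, speech-responsive
    channel selection), a unidirectional LSTM neural voice-activity
    detector trained with truncated backpropagation through time, a
    bidirectional LSTM decoder from neural features to 18 Bark-scale
    cepstral coefficients plus 2 pitch parameters, a deterministic
    vocoder over the same feature interface, a packetised streaming
    replay engine with publish/subscribe units and ring buffers, and
    analysis utilities: gradient saliency at predicted speech onset,
    acoustic-contamination auditing with permutation statistics and
    8-neighbour channel repair, mel-spectral correlation, and
    frame-level Levenshtein timing metrics. A synthetic-data module
    generates paired neural/audio/trial-log sessions so the whole
    pipeline runs end-to-end without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
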