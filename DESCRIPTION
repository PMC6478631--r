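Package: vocsynth
Title: Parametric Synthesis of Nonverbal Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A source-filter vocoder for human and animal nonverbal
    vocalizations (moans, screams, laugh syllables, roars and similar calls).
    The voiced excitation is built additively as a stack of sine-wave
    harmonics with a controllable spectral rolloff; turbulent noise is
    generated in the frequency domain; both are shaped by a vocal-tract
    transfer function derived from formant specifications or from vocal-tract
    length under the uniform-tube model, and applied by spectrogram
    multiplication.  Nonlinear vocal phenomena (jitter, shimmer,
    subharmonics, deterministic chaos) are driven by a thresholded random
    walk.  Control parameters are sparse time-value anchors, so a complete
    call fits in a short configuration.  Includes acoustic verification
    utilities (f0 tracking, spectral peak and rolloff measurement,
    spectrograms), a preset library, morphing between parameter sets, YAML
    configuration files, WAV output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    pracma,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
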