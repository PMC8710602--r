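Package: inferTRF
Title: Behaviorally Informed Stimulus Reconstruction from EEG with Backward
    Temporal Response Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding auditory selective attention in two-talker
    ("cocktail party") listening experiments. Extracts model-rate speech
    envelopes through an ERB-spaced gammatone filterbank with power-law
    compression, preprocesses EEG (2-8 Hz band-pass, 64 Hz), and fits backward
    temporal response functions (ridge-regression stimulus-reconstruction
    decoders) evaluated with leave-one-trial-out decoder averaging. Implements
    an "inferred" attended-stimulus model that combines keyword-recall
    responses with raised-cosine attentional-switch ramps to build a better
    estimate of the actually attended stream, plus a synthetic two-stream
    data generator (latent attention trajectories with difficulty-dependent
    switch hazards, behavioral responses with lapses, forward-modelled
    multichannel EEG) so the whole pipeline is testable without recorded data.
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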