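Package: megvad
Title: Voice Activity Detection from Multichannel Neuromagnetic Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end detection of per-sample voice/speech activity directly
    from multichannel neuromagnetic (MEG) recordings in a delayed overt-reading
    task. Provides a synthetic session generator with ground truth, epoching and
    preprocessing (gradiometer selection, robust artifact-trial rejection,
    two-level Daubechies-4 wavelet band restriction), acoustic ground-truth
    labeling (Wiener denoising plus an energy-based voice activity detector),
    segment-level RMS and framewise feature extraction, a polynomial-kernel SVM
    sanity check for isolated speech/non-speech classification, a long
    short-term memory recurrent sequence labeler trained with backpropagation
    through time and Adam for continuous per-sample prediction, and per-sample
    evaluation metrics with onset/offset timing-error and sensor-mode analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
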