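Package: selfrelEEG
Title: Self-Relative Evaluation of EEG-Based Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating EEG-based person-identification systems
    under an openness condition, in which novel subjects are gradually
    enrolled. Provides the full parameterized pipeline (common average
    referencing, Butterworth band-pass filtering, static overlapped
    segmentation, Burg autoregressive feature extraction, pluggable
    classifiers), a stochastic enrollment simulator, and self-relative
    degradation metrics (local and global relative loss, parameter power,
    and a decision-making metric) used to select the frequency sub-band and
    filter order carrying the most robust identity information. Includes a
    synthetic multichannel EEG cohort generator with band-localized,
    subject-specific autoregressive dynamics and minimal European Data
    Format (EDF) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    class,
    e1071,
    rpart,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
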