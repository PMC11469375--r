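Package: oromotorquant
Title: Quantitative Analysis of Orofacial Motor Function: Speech Acoustics, EMG, Kinematics and Swallowing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for quantifying the effect of a
    two-condition intervention (e.g. deep-brain stimulation OFF vs ON) on
    speech and swallowing. Implements spectrogram-based speech intensity,
    autocorrelation pitch tracking with glottal-pulse voice-break counting,
    smoothed cepstral peak prominence (CPPS), a linear-predictive-coding
    formant pipeline with per-vowel time-warped summaries, stimulation-
    triggered motor-evoked-potential and voluntary-EMG envelope
    area-under-the-curve metrics, facial-landmark kinematics and
    videofluoroscopic swallow metrics, and a percentile-bootstrap
    difference-in-means inference layer with multi-alpha confidence
    intervals. Ships a source-filter synthetic-data generator with known
    ground truth for every metric so the whole stack is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
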