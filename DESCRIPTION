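Package: betarebound
Title: Sensorimotor EEG Rhythm Analysis of the Somatosensory Beta Rebound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of event-related
    desynchronization/synchronization (ERD/ERS) of sensorimotor mu (8-12 Hz)
    and beta (13-30 Hz) rhythms in EEG, built around the attenuation of the
    post-stimulus beta rebound when lip somatosensory stimulation is paired
    with bilabial speech sounds. Provides a synthetic-data generator for the
    full experimental design (factorial speech-sound by lip-stimulation
    trials with EOG saccade responses), continuous-EEG preprocessing
    (band-pass, resampling, average reference, epoching, baseline
    correction), an EOG saccade detector for behavioral scoring, Morlet
    wavelet event-related spectral perturbation (ERSP) maps with a linearly
    ramped cycle count, sign-flip permutation statistics with
    Benjamini-Hochberg false-discovery-rate control, contrast-based
    within-subject 2x2x2 ANOVA with Bonferroni post-hoc tests, and a
    single-call pipeline with reproducible seeding. Minimal EDF and
    BrainVision readers and an EDF writer are included for interchange with
    standard acquisition systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
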