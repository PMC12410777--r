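Package: anxsig
Title: Multimodal Biosignal Analysis of Anticipatory Social Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for group analysis of multimodal psychophysiological
    recordings collected during anticipation of a social stressor. Provides a
    synthetic-cohort generator with ground truth (ECG, electrodermal activity,
    respiration, pupil size, head gyroscope, multi-channel EEG with ocular and
    powerline contamination, and GAD-7 style questionnaire scores), zero-phase
    per-modality preprocessing (bipolar derivations, tonic/phasic electrodermal
    split, EOG regression artifact removal, common average reference), Fourier
    resampling to a common rate, sliding-window epoching, per-epoch feature
    extraction (heart rate and variability, epoch means, respiratory rate, roll
    variance, Welch power spectral density and band power), and group statistics
    (median split on questionnaire change, exact Wilcoxon rank-sum tests per
    epoch and whole task, Cohen's d, Benjamini-Hochberg correction across
    channel/frequency grids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
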