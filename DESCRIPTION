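Package: eegmvpa
Title: Time-Resolved EEG Multivariate Pattern Analysis of Animacy
    Processing in Mild Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for time-resolved decoding of
    animacy (animal versus non-animal) from epoched multichannel EEG in
    healthy controls and patients with mild cognitive impairment.  Provides
    a synthetic epoched-EEG cohort generator with controllable group
    effects (onset/peak latency shifts, amplitude deficits, mean-matched
    pattern divergence), the six-stage preprocessing chain (average
    re-reference, ICA-based blink removal, epoching, baseline
    normalisation, 50 Hz low-pass, resampling), region-level ERP analysis
    with FDR correction, bin-sub-averaged linear SVM decoding with
    leave-one-bin-out cross-validation, pairwise-decoding representational
    dissimilarity matrices with multidimensional scaling, group
    classification from activation patterns and RDMs, and non-parametric
    inference (bootstrap, permutation, rank-sum, sign-rank, FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    ica,
    jsonlite,
    MASS,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
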