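Package: mfrest
Title: Within-Participant Detection of Brief Mindfulness Effects in Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting the neural effect of a brief mindfulness
    meditation exercise from resting-state EEG recorded before and after the
    exercise. Provides a seeded multi-channel EEG simulator with four
    resting-state conditions, an artifact-cleaning chain (Kaiser FIR
    band-pass, bad-channel rules, subspace reconstruction, segment
    rejection, linked-ear re-referencing, spherical-spline interpolation),
    Welch spectral band-power features, Wilcoxon rank-sum state comparisons
    over channels and brain regions, weighted sequential forward selection
    of (channel, feature) pairs with a class-balanced cross-validated cost,
    per-participant RBF-SVM classification with Monte-Carlo cross-validation,
    and a validation step comparing the pre/post score-density separation
    against temporal drift via symmetric Kullback-Leibler distances.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
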