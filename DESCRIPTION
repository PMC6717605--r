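Package: swallowscreen
Title: Cervical Accelerometry Swallow Screening: Reference Labelling,
    Signal Processing and Classifier Evaluation
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and evaluating accelerometry-based
    screening of oropharyngeal dysphagia. Derives binary swallowing
    safety and efficiency reference labels from videofluoroscopy
    ratings (Penetration-Aspiration Scale scores and pharyngeal residue
    fill percentages), applies per-stimulus and whole-protocol stopping
    rules, and summarises cohort prevalence and cumulative detection
    curves. Preprocesses dual-axis cervical accelerometry recordings
    with zero-phase Butterworth filters, segments swallow activity by
    dual-threshold hysteresis on an RMS energy envelope, extracts
    time-domain, spectral and wavelet features, and classifies impaired
    swallows with regularized linear discriminant analysis under a
    shared covariance matrix. Classifier accuracy is estimated by
    participant-stratified Monte-Carlo repeated random sub-sampling
    with bolus- and participant-level ROC/AUC and operating-point
    sensitivity and specificity. A synthetic-data subsystem simulates
    cohort outcome structure and burst-like swallow vibration signals
    with ground-truth annotations so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
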