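Package: fogkit
Title: Automated Detection of Freezing of Gait from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects freezing-of-gait (FOG) episodes in Parkinson's disease from
    tri-site inertial measurement unit recordings (lower back and both ankles,
    128 Hz accelerometer and gyroscope). Implements zero-phase low-pass
    filtering, annotation cleaning, overlapping window extraction with
    asymmetric FOG/non-FOG steps, an 86-feature spectral and time-domain
    library including the freezing index and back-to-legs ratio features,
    Bonferroni t-test screening with minimum-redundancy maximum-relevance
    (MRMR) ranking, patient-independent SVM-RBF classification validated
    leave-one-patient-out, episode reconstruction from overlapping window
    predictions, and derived outcomes (percent time frozen, episode counts).
    A built-in synthetic gait and freezing simulator generates three-site
    cohorts with scheduled trembling and akinetic episodes so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
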