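Package: ecgflow
Title: Single-Lead ECG Cleaning, Delineation, Diagnosis and Health Scoring
Version: 0.1.0
Authors@R:
    person("ecgflow", "developers", email = "ecgflow@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for 125 Hz single-lead (Lead I equivalent)
    electrocardiogram analysis: zero-phase filtering of high-frequency noise
    (50 Hz low-pass plus 60 Hz notch) and baseline wander (0.67 Hz high-pass
    plus moving-average baseline subtraction), lead-off/flat-line detection,
    Pan-Tompkins style QRS detection with P/QRS/T delineation and the standard
    interval measurements (P duration, PR, QRS, QT, QTc, T duration, atrial
    and ventricular rate), heart-rate-variability summaries and RR scatter
    data, a residual 1-D convolutional network with a recurrent head for
    multilabel diagnosis over 20 rhythm/conduction items (plus a reverse-lead
    binary variant), a rule-based cardiovascular health score with passive
    alert conditions, a seeded synthetic-ECG generator with analytic ground
    truth, WFDB/CSV input-output and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
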