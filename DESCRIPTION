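Package: ecgid
Title: Adaptive Threshold Filter Normalization for ECG Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject identification from single-lead (Lead-I)
    electrocardiograms acquired under motion, as in driver monitoring.
    Implements the full pipeline: a seeded multi-subject synthetic ECG
    generator with condition-dependent noise (sitting, slide touch,
    post-exercise, driving); Butterworth bandpass denoising, Pan-Tompkins
    R-peak detection, QRS-sparing moving-average smoothing and piecewise
    linear baseline removal; fiducial beat segmentation with fixed 0.3 s /
    0.4 s windows; construction of an ideal one-cycle ECG by first- and
    second-order interpolation of averaged P, Q, R, S, T vertices;
    selection of a per-subject sample cycle by maximum similarity to the
    ideal cycle; an adaptive integer-grid threshold filter that rejects
    motion-artifact-corrupted beats by Euclidean similarity; and 1:N
    identification with a nearest-template classifier or a built-in LSTM
    sequence classifier trained with RMSprop. Includes CSV and WFDB-style
    record I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
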