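Package: ppg2ecg
Title: Cycle-Based ECG Reconstruction from Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs electrocardiogram (ECG) waveforms from synchronized
    photoplethysmogram (PPG) recordings using a cycle-based linear pipeline:
    Savitzky-Golay smoothing, systolic/R-peak cycle segmentation (direct or
    semantically aligned), fixed-length resampling with amplitude
    normalization, energy-thresholded discrete cosine transform compression,
    and a closed-form ridge-regression transfer function between PPG and ECG
    coefficient spaces. Includes morphological (Pearson correlation) and
    temporal (R-peak delay) evaluation under general cross-validation,
    personalized sliding-window, and leave-one-subject-out protocols, and a
    paired PPG/ECG waveform simulator with ground-truth beat annotations.
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
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
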