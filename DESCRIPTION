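Package: gazepref
Title: Calibration-Free Webcam Gaze-Preference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame classification of a child's lateral gaze
    (left, right, center, distraction) from webcam video of the face,
    using image enhancement in CIELab/CMYK space, Prewitt-edge iris
    localization, and a sclera brightness-ratio rule, without any
    per-subject calibration. Aggregates per-frame labels into
    gaze-preference percentages for two side-by-side stimulus scenes
    (social versus abstract), calibrates the classification threshold
    against manual annotations by concordance, and computes the
    manual-versus-automatic validation statistics (frame-level Spearman
    correlation, two-sample proportion test, paired t-test) and
    group-comparison reports. Includes a synthetic face/eye/session/cohort
    generator with exact ground truth so the whole pipeline is testable
    without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
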