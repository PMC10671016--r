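Package: cmosdff
Title: Fluorescence Analysis for Implanted CMOS Dopamine-Sensor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse fluorescence recordings from an
    implanted needle-type CMOS image sensor monitoring a genetically encoded
    dopamine indicator (dLight) in the nucleus accumbens. Provides a
    ground-truth synthetic session generator emulating morphine-like,
    cocaine-like and saline dopamine kinetics on a 40 x 90 pixel sensor;
    per-pixel dF/F0 normalization against a pre-injection baseline; interval
    averaging and whole-image traces; region-of-interest detection by adaptive
    binarization, morphological cleaning and occupancy mapping; ROI trace
    heatmaps and drug-response profile metrics; and one-way repeated-measures
    ANOVA with paired post-hoc comparisons against the pre-injection control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
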