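Package: cmjump
Title: Countermovement Jump Height from Single-Camera Markerless Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures countermovement jump height from single-camera markerless
    motion capture (pose-estimation keypoint time series) and compares it against
    force-plate and optical motion capture ground truths. Implements the full
    post-processing chain: z-score spike removal and Savitzky-Golay smoothing,
    hip-peak jump segmentation, Fourier resampling onto a common time base,
    reverse-minmax and gravity-calibrated pixel-to-metric rescaling, toe
    displacement jump height, force-plate flight-time height, and agreement
    statistics (ICC(2,1) and Bland-Altman limits of agreement). Includes a
    synthetic multirate jump recording generator for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
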