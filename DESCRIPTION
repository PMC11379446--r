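Package: roatrack
Title: Spatiotemporal Tracking of Muscle Activity from High-Density Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds amplitude topographies from high-density surface EMG (HD-sEMG)
    electrode grids, tracks the weighted centroid of the region of activation (RoA)
    over a fatiguing isometric contraction, and quantifies the spatial redistribution
    of muscle activity with a suite of trajectory metrics adapted from centre-of-pressure
    postural-sway analysis (mean distance, path length, velocity, confidence ellipse and
    circle areas, swept area, spread). Includes torque-based contraction segmentation and
    endurance-time detection, amplitude (RMS envelope) and spectral-centroid (AIF)
    fatigue indices, a repeated-measures statistical battery (Friedman with Kendall's W,
    Wilcoxon post hoc with Bonferroni correction, endurance-time regression), and a
    synthetic HD-sEMG plus torque simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
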