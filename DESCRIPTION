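Package: gesturedtw
Title: Gesture Form Similarity from Pose Keypoints via Open-Begin-End
    Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the form similarity of co-speech gestures from
    video-derived 3D pose keypoint time series. Implements a preprocessing
    chain for MediaPipe-style normalized keypoints (linear interpolation of
    occlusion gaps, Gaussian smoothing, body-centered position and
    torso-length size normalization, aspect-ratio adjustment, y-axis
    inversion, wrist-relative fingertip positions), gesture stroke
    extraction with a minimum-duration rule, per-keypoint asymmetric
    open-begin-end dynamic time warping with frame-count normalization,
    gesturing-hand selection with a mirror-flip minimum rule for
    opposite-handed pairs, a synthetic dyadic gesture corpus generator with
    ground-truth feature-level similarity, and validation statistics
    (overlap counts, Spearman correlation with permutation p-values, a
    two-way within-estimator for dyad/item-adjusted slopes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
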