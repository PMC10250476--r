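Package: poseclass
Title: Behavior Classification from Markerless Pose Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for classifying animal behavior from video-derived
    keypoint time series. Reads pose tracks in the DeepLabCut CSV dialect,
    normalizes each frame into an egocentric reference frame (body at the
    origin, neck axis aligned), aligns frame-range behavior labels, segments
    the series into sliding windows, trains an imbalance-aware random-forest
    window classifier, evaluates it with blocked (non-shuffled) five-fold
    cross-validation and weighted F1, post-processes probabilistic
    predictions with pairwise behavior thresholds, and renders ethograms and
    subtitle-style overlay manifests. A deterministic synthetic pose-track
    simulator with seven pigeon behavior regimes makes the whole pipeline
    testable without any recording.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
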