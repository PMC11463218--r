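Package: fishtrack3d
Title: Dual-View 3D Fish Trajectory Reconstruction and Behavior Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detector-agnostic toolkit for reconstructing 3D trajectories of a
    fish in a box-shaped tank from two synchronized orthogonal camera views
    (top: X-Y plane, side: X-Z plane). Reads per-frame bounding-box detections
    in YOLO darknet txt or CSV form, maps detection centers through a
    declarative region-of-interest calibration into physical tank coordinates,
    merges the views on the shared X axis, fills short detection gaps by
    linear interpolation, and assembles uniformly sampled trajectories.
    Includes kinematic profiles (instantaneous velocity, cumulative distance),
    3x3x3 spatial occupancy statistics with layer summaries and heatmap
    encoding, IoU-matched detection metrics (accuracy, precision, recall) and
    coordinate-error statistics with model comparison, a seeded synthetic swim
    simulator with configurable surface-layer preference, detection dropout,
    localization noise and near-wall reflection false positives, and dynamic
    3D rendering with recency-based coloring.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
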