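# fishtrack3d

Reconstruct 3D swim trajectories of a single fish in a box-shaped tank from
two synchronized, orthogonal camera views — and compute the behavioral and
evaluation statistics that go with them.

Small-fish behavioral assays (zebrafish especially) are usually scored from a
single camera, which collapses the vertical dimension that carries much of
the behavioral signal (surface preference, diving, wall-hugging). A cheap
alternative to full stereo rigs is a *top* camera imaging the tank's X–Y
plane and a *side* camera imaging the X–Z plane. Any object detector that
emits per-frame bounding boxes (YOLO-style txt files or a CSV stream) can
then drive this package; no trained network or camera hardware is required
to develop or validate an analysis, because a seeded swim simulator stands
in for both.

## The method

Each view's detection-box center is mapped by a pure affine
(region-of-interest → tank plane) calibration into physical coordinates:
the top view yields (x<sub>t</sub>, y), the side view (x<sub>s</sub>, z).
The shared X axis joins them:

    x = (x_t + x_s) / 2,   y from the top view,   z from the side view,

with |x<sub>t</sub> − x<sub>s</sub>| recorded per point as a pairing
diagnostic. Frames missed by either detector become gaps; interior gaps of
at most `max_gap_frames` (default 5 frames = 0.5 s at 10 Hz) are filled by
per-axis linear interpolation, never extrapolated. On the assembled
trajectory the package computes:

- **kinematics** — instantaneous velocity (backward difference over the
  sampling interval) and cumulative distance, excluding steps that span
  unfilled gaps;
- **occupancy** — each tank axis split into three equal intervals → 27
  regions; per-region counts/proportions, lower/middle/upper layer
  summaries, and a bubble-heatmap encoding (radius ∝ proportion, dark blue →
  bright green);
- **detection evaluation** — IoU-matched confusion counts with
  accuracy = (Tp+Tn)/(Tp+Fp+Tn+Fn), precision = Tp/(Tp+Fp),
  recall = Tp/(Tp+Fn); per-frame Euclidean coordinate errors
  √((x₂−x₁)² + (y₂−y₁)² + (z₂−z₁)²) summarized as max/min/mean; and signed
  percent-change comparisons between two models' error statistics;
- **rendering** — 3-axis tank frames with recency coloring (last 1 s deep
  blue, 1–3 s light blue, older gray) and a cumulative-distance / velocity
  overlay.

## Worked example

```r
library(fishtrack3d)

geo <- example_geometry()              # 43 x 8 x 14 cm tank, two 1920x1080 views
cfg <- sim_config(seed = 42, n_frames = 600)   # one minute at 10 Hz
sim <- simulate_dataset(cfg, geo)
sim
#> Simulated dataset: 600 frames at 10 Hz
#>   top detections: 589   side detections: 594

pairs  <- pair_streams(sim$top_stream, sim$side_stream)
series <- reconstruct_sequence(pairs, geo$cameras, geo$tank, conf_threshold = 0.7)
traj   <- assemble_trajectory(fill_gaps(series, max_gap_frames = 5))
traj
#> 3D trajectory: 600 points at dt = 0.1 s (59.9 s span)
#>   observed 520, interpolated 80, unfilled gaps 0 (0 frames)

error_stats(traj, sim$truth)
#> n=600  err max 4.186 / min 0.005 / mean 0.139 cm

layer_summary(region_histogram(traj, geo$tank))
#>    layer count   pct
#> 1  lower   170 28.33
#> 2 middle    79 13.17
#> 3  upper   351 58.50
```

The 600 simulated frames include ~5 % dropout per view, 2 px localization
noise and occasional near-wall reflection false positives; the 0.7
confidence threshold removes most reflections before pairing. 520 frames
survive detection in both views, the 80 short gaps are interpolated, and the
reconstructed track sits on average 1.4 mm from the ground truth (the
occasional reflection that wins a frame accounts for the 4.2 cm worst
case). The fish spends ~58 % of its time in the upper layer, matching the
configured surface preference.

A command-line interface wrapping the same functions (simulate /
reconstruct / evaluate / stats / render) ships at
`system.file("cli", "fishtrack3d.R", package = "fishtrack3d")`.

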