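---
title: "Dual-view trajectory reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view trajectory reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishtrack3d)
```

This vignette documents the scientific model behind `fishtrack3d`, the
parameters that matter, and the places where the design was genuinely open
and a choice had to be made.

## Coordinate model and calibration

The tank is a box with the origin at the viewer's left-front-bottom corner:
X along the tank length (the axis both cameras share), Y along the width, Z
up toward the water surface. Each camera is described declaratively by its
image size and a region of interest (ROI): the pixel rectangle that frames
the tank in that view. The pixel-to-tank map is a pure per-axis affine
(proportional) transform of the ROI onto the physical plane. This assumes:

- the cameras are mounted square to the tank faces (no perspective skew),
- lens distortion is negligible over the ROI,
- refraction at the water surface and tank walls is ignored.

These are the standard working assumptions for small benchtop tanks imaged
from ~0.5 m with webcam optics; they are exactly what a checkerboard
calibration would relax, which is out of scope here. Because image v runs
downward, the side view sets `flip_v = TRUE` by default so that Z grows
toward the water surface; both flags are configurable since camera mounting
conventions vary.

The affine map is exactly invertible on the ROI interior (the test suite
checks round trips to below 1e-6 cm), and `tank_to_px()` is that inverse —
it is what the simulator uses to project ground truth into each view, so
reconstruction and simulation share one calibration model.

**Pixel slack.** Detection centers can fall marginally outside the ROI
(box quantization, detector jitter). Points up to `slack_px = 2` px outside
are clamped onto the ROI edge; farther out is treated as a per-frame
geometry error, recorded and skipped without aborting the run.

## View merging

The top view supplies (x, y), the side view (x, z). How the shared X should
be reconciled when the two views disagree is genuinely open: one could
average, trust one camera, or reject the frame. We average — it is
symmetric, unbiased under independent per-view noise, and halves the X
variance — and record the per-point disagreement |x_top − x_side|. A
disagreement above `x_tolerance_cm = 1` cm flags the point as a suspect
pairing (typically a reflection false positive that won a frame) while
still producing it, so downstream filtering is the caller's decision, not
silently ours.

## Gap filling

Detectors miss frames (motion blur, occlusion by reflections). A frame
missing in *either* view contributes no 3D point: both planes are required,
and the single-view observation is kept only as a diagnostic. Interior gaps
of at most `max_gap_frames = 5` frames (0.5 s at the 10 Hz default) are
filled by per-axis linear interpolation between the flanking observed
points and labeled `interpolated`. The cap avoids inventing behavior across
long occlusions; linear is the minimal-assumption interpolant and keeps
every filled coordinate inside the per-axis interval of its flanking
observations (a property the tests check over seeded simulations). Leading
and trailing gaps are never filled: interpolation yes, extrapolation never.

## Kinematics

Instantaneous velocity at sample *i* is the backward difference
(step length from sample *i−1* divided by the elapsed time); the first
sample's velocity is 0. Cumulative distance is the running sum of step
lengths. Steps that span an unfilled gap are excluded from both (velocity
`NA`, no added distance) so path length is never fabricated across
occlusions; `bridge_gaps = TRUE` straight-lines them for comparison.
Interpolated points do contribute: they lie on the straight chord between
observations and add no artificial length.

## Occupancy statistics

Each axis is split into three equal intervals, giving 27 regions. The
region id ordering — x fastest, then y, then z bottom-up,
`id = iz*9 + iy*3 + ix + 1` — is our documented convention. Interval edges
are half-open `[lo, hi)` with the final interval closed, so every point of
the closed tank box is classifiable and boundary points belong to the
higher interval. Layer summaries aggregate the 9 regions of each z third;
percentages are computed from counts and printed at 2 decimals. For the
published layer counts 4,556 / 3,265 / 10,669 of 18,490 this yields 24.64 %
/ 17.66 % / 57.70 %; a widely circulated 16.66 % figure for the middle
layer is inconsistent with its own count (the three printed percentages sum
to 99.0) and is therefore documented, not reproduced.

## Detection evaluation

Frames are scored by greedy best-IoU matching of confidence-filtered
detections against ground-truth boxes (IoU threshold 0.5 by default; greedy
is optimal when at most one truth box exists, the single-fish case). A
matched pair is a true positive, unmatched detections false positives,
unmatched truths false negatives, and an empty-truth, empty-detection frame
one true negative. With a single always-present animal, true negatives are
structurally 0 — which is why accuracy and recall coincide in such studies
(`(Tp+0)/(Tp+0+0+Fn) = Tp/(Tp+Fn)`); the test suite asserts this identity
on random counts. Metrics with zero denominators are reported as `NA`,
never coerced. Confidence thresholds are inclusive (≥), a choice the
boundary semantics of "confidence level" leave open.

Model comparisons report signed percent changes
`(final − initial)/initial × 100` computed from their inputs at full
precision (rounded to 2 decimals only for display). Published comparison
tables are accepted as printed via `error_stats_from_summary()`, which
deliberately enforces only min ≤ max: printed summaries sometimes violate
min ≤ mean ≤ max, which computed statistics cannot.

## The swim simulator

The simulator exists so that every pipeline stage is testable without
cameras or a trained detector. It emulates:

- **motion**: a correlated random walk at 10 Hz. Horizontal heading
  persists with parameter `persistence` (default 0.8) and turns by a
  uniform increment scaled by 1 − persistence; speed varies around
  `mean_speed_cm_s` (default 8 cm/s, a moderate cruising speed of roughly
  two body lengths per second for an adult zebrafish); walls reflect
  specularly. Vertical position follows a Metropolis-adjusted random walk:
  small proposals (sd 0.6 cm per frame) mixed with occasional darts
  (probability 0.15, sd 4 cm — burst swimming, well within the escape-swim
  range), reflected at floor and surface and accepted against the
  piecewise-constant layer-bias density. By construction its stationary
  layer occupancy is the configured `layer_bias` (default lower 0.246,
  middle 0.177, upper 0.577 — the strong surface preference reported for
  zebrafish), and the dart component makes mixing fast enough that a
  50,000-frame run estimates layer occupancy to within ~1 percentage point.
  `persistence = 1` is the documented ballistic limit: fixed 3D heading,
  specular reflections, no vertical steering — the deterministic case used
  for calibration tests.
- **detection degradation**: per-frame Bernoulli dropout per view (default
  0.05), Gaussian pixel noise on box centers (default sd 2 px), and
  confidences drawn from Beta(20, 1) for real detections;
- **reflection false positives**: when the fish is within
  `wall_margin_cm = 1.5` cm of a wall of the view plane, a false detection
  mirrored across the nearest ROI edge in pixel space appears with
  probability `reflection_p` (default 0.1) and a Beta(4, 2) confidence.
  The Beta split means a 0.7 or 0.9 confidence threshold separates real
  detections from reflections meaningfully, mirroring how such thresholds
  are used in practice.

All randomness flows from the single config seed (the two views use
seed + 1 and seed + 2 so they degrade independently but reproducibly), and
identical configs are bit-reproducible.

What the simulator does **not** emulate: schooling or any multi-animal
interaction, behavioral states (freezing, thigmotaxis episodes), water
refraction optics, detector-specific error correlations (e.g. confidence
dropping near walls), or frame-timing jitter. Passing tests therefore
demonstrate that the *pipeline* is correct and well-behaved under
controlled degradation — not that any particular detector will achieve a
given accuracy on real video.

## Numerical choices

- Timestamps are always `frame_index × dt` (dt default 0.1 s); file
  modification times are ignored. Frame indexing is 0-based.
- Equal confidences tie-break to the earlier line (stable file order).
- The zero-noise reconstruction floor is the physical extent of one pixel
  after the ROI→tank map (~0.027 cm along X for the bundled geometry);
  round-trip tests assert errors below this quantization bound.
- `assemble_trajectory()` rejects series whose timestamps deviate from the
  uniform grid by more than 1e-6 s.
- Degenerate inputs error loudly: all-empty series, empty histograms,
  all-zero confusion counts, tanks with non-positive dimensions.

## Problem sizes

The test suite exercises the full pipeline at the study scale it mirrors:
18,490 synchronized pairs for the conservation check, 10,000 frames for the
zero-noise round trip, 50,000 frames for occupancy recovery, and 5 seeds ×
4 noise levels × 1,500 frames for noise monotonicity. These sizes give the
Monte-Carlo margins the assertions need (e.g. ±3 percentage points on layer
occupancy) while keeping a full run in tens of seconds.

## Known limitations

- A single animal only; associating detections across individuals is a
  different (data-association) problem and out of scope.
- The affine calibration cannot represent perspective or refraction; for
  rigs where those matter, a projective calibration would need to replace
  `px_to_tank()`.
- Linear gap fill underestimates path curvature inside gaps; cumulative
  distance is accordingly a lower bound over interpolated stretches.
- The X-averaging merge assumes both views are equally trustworthy on X;
  rigs with very different pixel scales per view might prefer a weighted
  mean.
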