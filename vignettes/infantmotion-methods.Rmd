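---
title: "Methods: markerless infant movement analysis from single-camera video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless infant movement analysis from single-camera video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantmotion)
```

## The problem

The quality of an infant's spontaneous ("general") movements is an early
marker of neurodevelopmental outcome, but its clinical assessment is
qualitative and requires trained observers. `infantmotion` implements a
semi-automatic pipeline that turns an ordinary single-camera recording of a
supine infant into a battery of quantitative movement features, along two
complementary routes:

1. **Trajectory analysis** — one reference point per end effector (right
   hand, left hand, right foot, left foot) is tracked frame by frame,
   normalized anthropometrically, and summarized by kinematic features.
2. **Motion-image analysis** — frame differencing segments the pixels that
   changed between consecutive frames, and the amount and location of change
   is summarized globally, with no tracking involved.

A synthetic scene generator with exact ground truth makes every stage
testable without access to clinical recordings.

## Calibration and units

A single camera cannot give absolute distances, so all trajectory
coordinates are expressed in *head lengths*: the operator marks the
forehead-to-chin line once per video, and its pixel length becomes the unit.
The operator also marks the body symmetry line (clavicle midpoint to
pelvis); all trajectories are rigidly rotated about its midpoint so that the
symmetry line maps onto the image +y axis with the head toward smaller y.

Features are computed in this normalized, reoriented frame. Reorientation
matters for the per-axis features: without it, the split of a feature into
x and y components would depend on arbitrary camera roll, whereas after it
x means medio-lateral and y cranio-caudal for every video. Rotation is
rigid, so speeds, cross-correlations and pooled periodicity are unaffected;
only the per-axis decompositions change.

Pixel coordinates are 0-based, x = column, y = row, origin at the top-left
pixel center. Conversion of color frames to grayscale uses the ITU-R BT.601
luma weights (0.299, 0.587, 0.114).

## Tracking

Each end effector is tracked by a pyramidal translation-only
Kanade–Lucas–Tomasi tracker (2 pyramid levels, iterative Gauss–Newton
refinement with bilinear sampling). The template is the patch around the
point in the last valid frame, with side `0.1 * head_length`, odd-rounded,
floored at 9 px — the floor keeps enough appearance structure in the
template when calibrations are small; real recordings have head lengths of
hundreds of pixels.

A proposed match is accepted only if it passes three gates:

* **Search window** — the match must lie in the axis-aligned square of side
  `0.25 * head_length` centered on the previous point. This is a hard
  constraint, not a hint; it caps the per-frame displacement.
* **Appearance residual** — the mean absolute intensity difference between
  template and matched patch must not exceed 25 (on the 0–255 scale). This
  gate detects the tracked appearance vanishing, e.g. a hand slipping under
  a blanket: without it, frame-to-frame tracking can lock onto the static
  background with a near-zero forward–backward error.
* **Forward–backward error** — tracking the match back to the template
  frame must return within 1 px of the starting point.

The interactive operator of a GUI workflow is replaced by a *reset
provider*: a callback consulted whenever a match is rejected. It may supply
a new point (recorded as a *reset* — the unit of the failure-rate
statistic), declare the limb invisible (*skip*), or abstain. After a skip
the last valid point is kept as the anchor, so a limb that reappears where
it vanished is re-acquired automatically and without a reset; after an
abstention tracking stays suspended until the next supplied point. Scripted
providers replay recorded sessions from CSV; ground-truth-backed providers
serve the synthetic benchmarks. The quality-gate design (residual +
forward–backward) is the package's own, since "tracking failure" has no
canonical definition for single-point KLT; both thresholds are exposed.

The failure rate of a trajectory is `100 * resets / N`, excluding the
initial selection at frame 0; skips are not failures.

## Trajectory preprocessing

After normalization and reorientation, interior runs of at most 5
consecutive missing samples are filled by linear interpolation; longer runs
and runs touching either end are left missing (never extrapolated). At the
nominal 12.5 Hz sampling rate this caps interpolation at 400 ms. Valid
samples are never altered.

## Kinematic features

With `p_t` the point at frame `t` (head lengths) and `N` frames:

* **Velocity** `v_t = ||p_t − p_{t−1}||`, defined where both frames are
  valid, smoothed by a third-order low-pass Butterworth filter with cutoff
  at 95% of Nyquist. The filter is applied zero-phase (forward–backward)
  per contiguous valid segment, with odd-reflection padding and
  steady-state initial conditions, so a constant series passes through
  exactly unchanged — the plain zero-padding forward–backward scheme leaves
  visible edge transients at this cutoff. Segments shorter than three times
  the filter order are left unfiltered and counted. Units: head lengths per
  frame; per-second values are `fps` times larger.
* **Acceleration** `a_t = v_t − v_{t−1}` on contiguous speed segments.
* **Cross-correlation** per limb pair: `CC = cov(v1, v2) / sqrt(var(v1)
  var(v2))` over the common defined frames — a zero-lag synchrony index in
  [−1, 1]. Undefined for overlaps shorter than 2 samples or constant
  series. The smoothed speeds are used by default (`cc_filtered = FALSE`
  gives raw speeds); smoothing is part of the velocity definition here.
* **Area from moving average** per limb and axis: the centered moving
  average over a window of `k = 30` samples is subtracted and the absolute
  deviations are summed over the frames with full window support. The
  centered window holds `k + 1` samples and the mean divides by `k + 1`: a
  30-sample divisor over 31 points (available as `literal = TRUE`) would
  give a constant series a nonzero score, which contradicts the meaning of
  the statistic as a smoothness measure, so the true mean is the default.
  The window is specified in samples; 30 samples ≈ 2.4 s at 12.5 Hz.
  Totals for upper (both hands, x + y) and lower (both feet) limbs are also
  reported.
* **Periodicity** per limb: each axis is split into non-overlapping
  500-sample windows (40 s at 12.5 Hz; a trailing partial window is
  discarded so the statistic is comparable across recording lengths), the
  window mean is computed, and crossings of the series with that mean are
  detected between samples of strictly opposite sign. Samples exactly on
  the mean adopt the sign of the nearest preceding off-mean sample (leading
  ties take the following sign) — a tie rule is needed because sampled
  series can touch the mean exactly. Distances between consecutive
  crossings are pooled over both axes and all windows; the summary is
  `d_bar` (mean), `sigma_d` (population SD), `t_in` (total crossing count)
  and `P = 1 / (d_bar + sigma_d)`. Per-axis summaries are retained, because
  the z-contribution analysis needs them. Crossing chains are broken at
  missing samples. Positions, not smoothed speeds, enter this statistic.

Any feature that cannot be computed is `NA` — an explicit undefined marker,
never a silent zero.

Useful invariances, all exercised in the test suite: CC, periodicity,
`t_in` and `d_bar` are amplitude-invariant; mean velocity and the area from
moving average scale linearly with amplitude (so doubling the head length
at calibration halves them exactly); the interpolator never touches valid
samples.

## Motion images

For each pair of consecutive grayscale frames: absolute difference → 5×5
median filter (salt-and-pepper removal) → binarization at `> 15` on the
0–255 scale → 3×3 equally weighted averaging → re-binarization. The final
re-binarization keeps a pixel iff its 3×3 neighborhood mean is at least
5/9 — a majority vote that deletes isolated pixels and preserves block
interiors; some rule is needed because an averaging kernel applied to a
binary image does not return a binary one. Both filters use
symmetric-reflection borders. The fixed threshold (15) is configurable, and
an Otsu-based automatic mode is available as a convenience beyond the
fixed-threshold protocol.

From the binary motion image: the **quantity of motion** `Q` is the moving
pixel fraction, and the **centroid of motion** `C` is the centroid of the
single cluster found by a one-cluster k-means on the moving pixels — which
is exactly their coordinate mean (the tests verify the equivalence against
`stats::kmeans` runs). Summary statistics cover `Q` (mean, SD, max), `C`
(per-axis mean and SD, in pixels — these features are deliberately not
normalized), and the centroid's speed and acceleration with gaps breaking
the chain. A consequence of the median filter worth knowing: change bands
narrower than about 3 px (fewer than 13 of the 25 window pixels) are
erased, so very slow motion of small structures produces empty motion
images.

## Reliability statistics

* **Trajectory correlation**: per limb and axis, the zero-lag Pearson
  correlation between two operators' pixel-space trajectories over frames
  valid in both. A trend comparison: constant positional offsets between
  operators do not matter, which is why raw pixel trajectories are used.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement, from the two-way ANOVA mean squares
  `(MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))`. Point estimate
  only. `compare_operators()` applies it per scalar feature across videos.
* **z-axis contribution**: for depth-augmented trajectories (N×3), the
  percentage `100 f_z / (f_x + f_y + f_z)` per limb for the per-axis
  features (area from moving average, crossing count, mean crossing
  distance, periodicity). The package does not acquire or register 3D
  data; it accepts already-3D trajectories.

## The synthetic generator

`scene_spec()` / `render_scene()` emulate the relevant structure of a
nursery recording at desk scale: a static low-contrast textured background
(the blanket — giving the tracker realistic texture to reject), four
anti-aliased disc blobs (the end effectors) moving along analytic
trajectories, occlusion modeled by not drawing a blob for an interval, and
Gaussian plus salt-and-pepper pixel noise. One RNG stream per component
(background, noise, rater jitter) is derived from the master seed, so
toggling noise never changes trajectories, and a fixed seed gives
bit-identical videos.

The defaults are the package's reference benchmark condition: 160×120 px,
12.5 Hz, 60 s (750 frames), head length 24 px, four sinusoidal limbs with
periods 3.2–6.4 s and amplitudes up to 12 px (peak speeds ≈ 1.9 px/frame,
safely inside the 6 px search window), noise off. These sizes keep the
full benchmark comfortably within an interactive workflow while preserving
the geometry ratios of a real recording (blob diameter ≈ one third of head
length; excursions ≈ one head length).

What the generator does *not* emulate — and hence what passing benchmarks
do not demonstrate: articulated, deforming limbs; illumination changes;
camera motion; motion blur; an infant's torso as moving background; partial
(as opposed to total) occlusion. Results on the benchmark bound the
tracker's numerical behavior, not its clinical robustness.

`make_rater_pair()` jitters the ground truth with two independent Gaussian
streams, emulating two operators' click noise — which perturbs initial
conditions and resets, the operator-dependent part of the real workflow —
for exercising the reliability statistics end to end.

## Numerical choices and degenerate inputs

* Butterworth at 0.95 Nyquist: zero-phase with steady-state initialization
  (see above); the design comes from `signal::butter`, the application is
  implemented here.
* Crossing detection ties: exact equality with the window mean, resolved
  leftward; in floating point, exact ties are rare and the rule mainly
  protects constant plateaus.
* Moving-average support: only frames whose full `k + 1` window is inside
  the recording (and free of missing values) contribute.
* Degenerate inputs are errors or flagged `NA`s, never silent zeros:
  coincident calibration endpoints, fewer than 2 frames, empty motion
  images, constant series for correlation, fewer than 2 crossings for
  periodicity.
* Tracking is deterministic: identical video + provider script gives an
  identical trajectory.

## Known limitations

* Video I/O supports image-sequence directories (PNG/TIFF); container
  formats (AVI/MP4) must be exploded to frames with an external tool
  (e.g. ffmpeg) first.
* The tracker is translation-only; rotation and deformation of the tracked
  patch are absorbed by the template update from frame to frame, which can
  drift on deforming targets.
* Periodicity requires at least one full 500-sample window (40 s at
  12.5 Hz); shorter recordings get `NA`.
* The ICC is reported without confidence intervals.
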