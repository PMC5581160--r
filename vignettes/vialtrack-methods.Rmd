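---
title: "vialtrack: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vialtrack: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Climbing ("negative geotaxis") assays score the startle-induced upward walk
of flies in vertical vials. Classical versions record only the height
reached after a tap. `vialtrack` instead parameterises the full walking
behaviour from short video: a fixed 640 × 480 camera films up to four
75 × 13 mm vials at 30 frames/s for 10 s immediately after the rack is
tapped, two consecutive recordings per vial are averaged, and recordings are
repeated over the cohort's lifetime while deaths are logged at each food
transfer. Because flies die during the experiment, every vial-level total is
normalized by the number of flies actually present, which the detector
estimates from the video itself.

## Detection model

* **Background** — per-pixel temporal median over up to `max_samples` (25)
  evenly spaced frames. A pixel occupied by a fly in fewer than half of the
  samples recovers the empty plate, so no fly-free reference image is
  needed. This fails only if a fly is stationary on one spot for more than
  half the recording; over 10 s of post-startle behaviour that is rare.
* **Vial segmentation** — backlit tubes are bright vertical strips.
  Columns whose mean intensity exceeds the global Otsu split form bands;
  the `n` widest bands are the vials, ordered left to right, and the row
  profile of each band fixes its vertical extent.
* **Calibration** — the known tube length (75 mm) spans the strip height:
  `mm_per_px = 75 / (y_max_px − y_min_px)`, assumed isotropic. The tube
  width (13 mm) serves only as a consistency check (warning beyond 10%).
  Height above the tube bottom, not image row, is the physical `y`.
* **Blob detection** — signed subtraction `background − frame` (flies are
  dark on bright tubes, polarity fixed), threshold `contrast_min` (25
  intensity units), 8-connected components with area in [4, 400] px,
  contrast-weighted centroids. Occlusion merges blobs; merged blobs are
  left as single detections, and identity recovery is the tracker's job.
* **Fly count** — the modal per-frame detection count over the recording,
  ties broken toward the larger count because occlusion makes undercounts
  likelier than overcounts.

## Tracking model

Detections are linked frame by frame. Each live track predicts its next
position as its last observed position — a deliberate constant-position
model: at 30 fps a fly moves ≈ 0.3 mm between frames, far less than typical
inter-fly spacing, and a velocity model would mostly amplify detection
noise. Matching minimises total Euclidean distance (Hungarian method,
implemented in the package and checked against brute-force permutation
enumeration) under a gate of `gate_mm_per_s / fps` per elapsed frame
(default 60 mm/s ≈ 10× the highest mean velocities seen in aged-fly
panels). Unmatched detections open tracks; tracks unseen for more than
`max_gap_frames` (3) close; shorter gaps are filled by linear interpolation
flagged `interpolated`; tracks below `min_track_frames` (15 ≈ 0.5 s) are
dropped as flicker. Identity switches during crossings are accepted, not
repaired: every reported descriptor is an identity-agnostic aggregate, so a
switch merely re-partitions the pooled frame set (it can bias episode
counts slightly; see limitations).

## Descriptor definitions

Raw speed is `||p_{i+1} − p_i|| · fps`, smoothed with a centred 5-frame
moving average (truncated at the ends). Smoothing suppresses the ±0.5 px
quantization jitter that would otherwise inflate motion descriptors;
window 5 (0.17 s) is well below pause/walk bout durations.

Two thresholds with different semantics:

* `motion_cutoff_mm_s = 2.5`: a frame counts as *in motion* only strictly
  above the cutoff ("faster than"), pooled over all traces of the vial.
* `walk_threshold_mm_s = 2.0`: a *walking episode* ("trajectory") is a
  maximal run of frames at or above the threshold (speeds *below* 2 mm/s
  are not progressive movement); runs shorter than `min_episode_s` (0.2 s)
  are discarded. The threshold applies to episode membership only — the
  speed trace itself is never floored.

Per vial: pooled mean and max velocity; total walking duration = Σ episode
durations / fly count; total walking distance = Σ episode path lengths
(vial total, raw displacements); mean trajectory length = distance / fly
count; mean trajectory length per episode = distance / episode count;
`n_trajectories` = episode count (so that count × per-episode length =
total distance exactly), with `mean_trajectories_per_fly` as the
normalized companion figure. Replicate recordings are averaged field-wise;
the recorded fly count is the minimum of the two, flagged when unequal.

Pooled (rather than per-fly-then-averaged) velocity moments were chosen
because they are invariant to identity switches; with equal-length tracks
the two definitions coincide.

## Synthetic arena

The simulator is the package's ground-truth instrument, not a visual
mock-up. Each fly is an independent two-state Markov chain: per frame a
paused fly starts walking with `p_start_walk` (0.2) and a walking fly
pauses with `p_stop_walk` (0.05), giving 0.8 stationary walk occupancy,
mean walk bouts of 0.67 s and pauses of 0.17 s — brisk post-startle
behaviour. Episode speeds are drawn once per bout from a positive-truncated
normal (mean 8, sd 2 mm/s, chosen so pooled mean velocities land near the
5–6 mm/s of healthy young flies); headings blend the previous direction
with a fresh uniform one (persistence 0.8); a constant upward drift of
2 mm/s models the startle-induced climb and stays active for the whole
10 s, since recordings start immediately after tapping (the protocol does
not state the delay; this is the free-parameter choice). Walls reflect.

Rendering projects mm positions into a bright strip per vial (background
200, field 20) and draws each fly as an anti-aliased dark disc (level 40,
radius 3 px); Gaussian pixel noise (sd 3) is added and clipped. The
anti-aliased edge is what makes sub-pixel centroid recovery possible —
with hard-edged discs the quantization error is a full ±0.5 px.

`min_separation_mm` (default 2.5, i.e. non-overlapping blobs) enforces the
unambiguous-count fixture regime by rejection: initial positions are
re-drawn, and a move that would violate the separation makes the fly turn
to a fresh heading (up to 8 tries) instead of being dropped. The
turn-away rule matters: pure move rejection lets adjacent flies lock each
other motionless, after which the median background absorbs them — an
artifact of the sampler, not a behaviour of startled flies. Set
`min_separation_mm = 0` to study occlusion.

What a green test establishes: that the pipeline recovers the descriptors
of *this* stated world (distinct pause/walk bouts, rigid dark discs,
static background, no depth) to within 5% on noise-free renders. It does
not establish robustness to wing posture, reflections off the tube wall,
condensation, depth-dependent scale (the 3-D tube is projected flat), or
fly–fly interactions — none of which the renderer emulates.

## Statistics

Kaplan–Meier product-limit estimation with the restricted-mean convention
(area under S(t) up to the largest event time; with no censoring this is
exactly the arithmetic mean); median = smallest t with S(t) ≤ 0.5; maximum
= largest death time. Deaths are recorded on the transfer day they are
observed (no interval-midpoint imputation); flies alive at the end or lost
(e.g. having lost climbing ability) are right-censored at last
observation. Two-group comparisons use the standard log-rank chi-square
(1 df) with hypergeometric variance; its type-I calibration is asserted by
simulation in the acceptance suite.

Group comparisons of descriptors use per-descriptor one-way ANOVA followed
by Fisher's LSD with the pooled within-group mean square. This replaces a
multivariate GLM deliberately: per-descriptor significance is what the
panel figures report, and the univariate route reproduces that structure
with far less machinery. Degenerate inputs are defined by convention:
all-identical constant groups give F = 0, p = 1; zero within-variance with
distinct means gives F = ∞, p = 0. LSD pairs are flagged only when the
omnibus F is significant at the 95% level (the "protected" procedure).

## Numerical conventions

* Speed–threshold comparisons carry an absolute tolerance of 1e-9:
  positions accumulated step by step hold ~1e-13 rounding noise, which
  would otherwise flip the stated boundary behaviour at exactly 2.0 or
  2.5 mm/s. The tolerance is ~10⁴ × the noise and ~10⁻⁹ × any intended
  speed difference.
* Frame indices are 0-based (`t_s = frame / fps`); vial and fly ids are
  1-based. The frame index, not the timestamp, is authoritative.
* Gated assignment uses a large finite penalty (1e9) for out-of-gate
  pairs, then strips such pairs from the solution, which maximises the
  number of in-gate matches before minimising summed distance.
* Tracks re-acquired after g missed frames are gated at (g+1) × the
  per-frame gate, honouring the per-interval displacement bound.
* CSV tables are comma-separated, UTF-8, '.' decimal, header mandatory;
  round trips are exact to ≥ 6 decimals.
* All simulation randomness derives from one integer seed (stage seeds are
  mixed deterministically and stay below 2³¹); identical seeds give
  bit-identical trajectories, frames and output tables.

## Known limitations

* Episode *counts* are not monotone in the walk threshold (raising it can
  split an episode in two); only durations and percent-in-motion carry a
  monotonicity guarantee.
* Constant-position prediction can swap identities when flies cross within
  the gate; episode counts inherit a small bias under heavy crossing.
* A fly pausing on one spot for more than half the recording is absorbed
  into the median background and temporarily lost.
* Video containers (AVI/MP4) are not read directly — extract frames to a
  PNG directory first; no video codec library is available in the
  supported dependency set.
* The mm scale is isotropic from tube height only; lens distortion and
  perspective are uncorrected.
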