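---
title: "Measuring gesture form similarity with open-begin-end DTW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gesture form similarity with open-begin-end DTW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesturedtw)
```

## What the package measures

Two speakers describing the same object often produce gestures that
resemble each other in *form*: handshape, movement, orientation, and
position in gesture space. Human coders can rate this feature by
feature, but slowly and categorically. `gesturedtw` computes a
continuous dissimilarity score from pose-tracking output: the smaller
the score, the more alike two gestures look. This vignette explains the
model behind the score, the parameters that matter, the synthetic data
the package validates itself on, and the numerical choices a user should
know about.

## Input model

A recording is a `skeleton_ts`: per-frame (x, y, z) coordinates for 16
landmarks — each hand's wrist and five fingertips, plus two shoulders
and two hips — in normalized image units as produced by video pose
trackers (each axis nominally 0–1, y growing downward, z a monocular
depth heuristic). Occluded keypoints are missing values, not zeros.
Gesture strokes arrive as a segment table (seconds, half-open windows,
handedness ∈ {left, right, both}). Stroke times map to frames as
`round(t * fps)` with a 0-based half-open `[start, end)` convention —
the files leave this implicit, so the package fixes one convention and
applies it everywhere.

## Preprocessing chain

Applied in a fixed order by `run_pipeline()`:

1. **Interpolation** (`interpolate_missing`). Interior occlusion gaps are
   filled linearly — `c(1, 2, NA, NA, 5)` becomes `c(1, 2, 3, 4, 5)` —
   and leading/trailing gaps copy the nearest observation. A track with
   no observations at all is an error naming the landmark, so callers
   can decide to drop it.
2. **Smoothing** (`smooth_series`, σ = 2 frames by default). A
   discretized Gaussian kernel truncated at 4σ and renormalized, with
   reflect-about-edge padding, damps tracker jitter. σ is in frames, so
   at 50 FPS the same σ smooths a shorter physical window; σ = 0
   disables smoothing.
3. **Position normalization** (`normalize_position`). The mid-torso
   (mean of both shoulders and both hips) is subtracted per frame, so
   standing position and camera placement drop out. The torso points are
   means/midpoints because trackers name no such landmarks directly;
   mid-shoulder and mid-hip are the midpoints of the respective pairs.
4. **Size normalization** (`normalize_size`). All coordinates are
   divided by the torso length — the 3D mid-shoulder-to-mid-hip
   distance — so body size and camera proximity drop out and the torso
   measures one unit. Two choices deserve a note. First, the scale
   factor is applied as a *division*: scaling by the raw torso distance
   itself would amplify, not remove, apparent-size differences, so the
   factor is read as the reciprocal of torso length. Second, the torso
   length is the *median across frames* of the per-frame distance,
   which keeps a single-frame tracking glitch from rescaling the whole
   recording; centering stays per-frame.
5. **Aspect-ratio adjustment** (`adjust_aspect`). x is multiplied by
   16/9 (exactly, not the rounded 1.78) so equal physical displacements
   give equal coordinate displacements on both axes of 16:9 video. z is
   never aspect-adjusted.
6. **y-inversion** (`invert_y`). Image y grows downward; negating it
   makes larger y mean higher in space. An involution.
7. **Relative fingertips** (`relative_fingertips`). Each fingertip is
   re-expressed as fingertip − same-hand wrist. Handshape and hand
   orientation end up encoded in the fingertips, hand position in the
   wrist, so position misalignment does not leak into handshape
   comparisons.

The composition is invariant to global translation (to 1e-9) and global
rescaling (to 1e-6) of the input — both are tested as properties.

By default only (x, y) enter the distance: the aspect correction is
defined for the image plane and monocular z is a heuristic the package
does not trust by default (`use_z = TRUE` opts in). Whether the original
analyses used 2D or 3D coordinates inside the alignment is not
something the data formats record; both are supported.

## Stroke extraction and the minimum-duration rule

Very short clips give unstable alignment distances, so clips shorter
than 330 ms — ten frames at 30 FPS, seventeen at 50 (the rule is stated
in milliseconds and converted with a ceiling) — are lengthened with
*real* surrounding frames from the recording, split as evenly as
possible before and after the stroke. Two boundary decisions are the
package's own: an odd deficit puts the extra frame *after* the stroke
(retraction frames tend to resemble stroke kinematics more than
preparation frames do), and when one side hits the recording edge the
remainder comes from the other side. Padding never fabricates frames; a
recording shorter than the minimum is an error.

## The distance

`dtw_open_begin_end()` aligns a query trajectory (n frames) to a
reference (m frames) under the asymmetric step pattern: every step
advances the query by exactly one frame and the reference by 0, 1, or
2, so each query frame is matched exactly once and the cumulative cost
is a sum of n local Euclidean costs. Open begin lets the path enter the
reference at any column at no cost; open end takes the minimum over the
final query row. This forgives imprecise stroke boundaries — an exactly
embedded query costs zero regardless of non-matching flanks.

Determinism: ties at the open end resolve to the smallest ending
column; ties during backtracking prefer diagonal over
repeat-reference-frame over skip. Identical inputs always yield
identical output.

The cumulative cost is normalized by `n + m`, the total frame count of
the two clips, so longer gestures are not penalized for length. A note
on this denominator: normalization conventions for the asymmetric
pattern elsewhere divide by n alone; this package follows the
total-frame-count definition and states it in the run log, since the
two differ by a factor that would matter when comparing absolute
distance values across software.

Per compared hand, the distance is computed separately for the six hand
keypoints and averaged (`hand_distance`). The first clip of a pair
serves as the query; asymmetric DTW is not symmetric in its arguments,
so the choice is logged, and `symmetrize = TRUE` averages both
directions for users who prefer a symmetric score.

**Gesturing-hand selection** (`pair_distance`): only gesturing hands
enter the score. Two-handed vs two-handed averages left–left and
right–right; same-side one-handed pairs compare that side; opposite-side
one-handed pairs compare cross-hand. For a one-handed vs two-handed
pair the data formats define no rule, so the package takes the minimum
over the single hand vs each of the other speaker's hands and flags the
branch in the output.

**Mirror rule** (`mirrored_pair_distance`): people readily perceive a
left-handed gesture and its right-handed mirror image as similar, but a
cross-hand trajectory comparison does not. For opposite-handed
one-handed pairs, the second clip is mirror-flipped (x negated about
the body midline, left/right labels swapped — an involution on centered
coordinates) and the lower of the original and flipped distances is
adopted; ties keep the original and the `mirror_used` flag records the
choice. Flipping operates on the preprocessed, centered coordinates; no
re-preprocessing is needed because every pipeline step commutes with
the reflection.

## Synthetic corpus generator

`generate_corpus()` builds dyadic corpora with known ground truth so
every stage is testable without recordings. Each pair starts from a
random base gesture — a wrist trajectory (line, arc, circle, or zigzag)
anchored in gesture space, fingertips riding along as a rotated
handshape template (open, fist, C-shape, point, pinch), a torso with
gentle postural sway, a resting opposite hand — rendered at 30 or 50
FPS with Gaussian tracking noise (sd 0.004 image units) and occlusion
gaps (one gap in ~5% of landmark tracks, never a whole track). Speaker
B's gesture perturbs zero or more of the four features: handshape swaps
the template, movement changes the trajectory kind and reverses the
heading, orientation rotates the template by π/2, position shifts the
anchor by 0.12 image units in a random direction. Unperturbed features
are annotated similar (1), perturbed ones not (0) — annotations are
deterministic given the flags, emulating a careful coder rather than a
noisy one.

The number of perturbed features per pair is drawn from
{0: .40, 1: .35, 2: .13, 3: .07, 4: .05}, making ~74.5% of all feature
ratings "similar" — matching the share observed in annotated corpora of
this kind — while still covering the full 0–4 overlap range in any
moderate corpus. A share of one-handed pairs (15%) is rendered
mirrored: speaker B uses the opposite hand with mirrored geometry,
which by construction makes the flipped comparison the right one. The
perturbation magnitudes were fixed once with a sweep
(`tools/tune_magnitudes.R`) showing each single-feature perturbation
separates cleanly from matched unperturbed pairs; they are committed as
constants.

What the generator does *not* emulate: camera-angle distortion between
speakers, correlated (non-Gaussian) tracker error, anatomically
plausible finger articulation, co-speech timing, or rater disagreement.
Passing the recovery tests therefore shows the pipeline's machinery is
sound — not that any particular correlation level carries over to real
recordings, where the correlation between distance and human coding is
known to be much weaker.

## Validation statistics

- `overlap_count()`: sum of the four binary feature ratings (0–4);
  ordinal 0–5 ratings binarize first (4–5 similar, 0–3 not); handedness
  never enters because the distance already conditions on gesturing
  hands.
- `spearman_cor()`: rho is the Pearson correlation of average ranks.
  The p-value route depends on n: exhaustive permutation enumeration
  for n ≤ 8 (n! is infeasible much beyond that), Monte Carlo
  permutation up to n = 20, and the t approximation beyond. The
  exhaustive p is discrete and tie-inclusive, hence valid but
  super-uniform at tiny n — a property of any discrete test, worth
  knowing when interpreting very small samples. Calibration of the
  Monte Carlo route is verified by a uniformity test under
  independence.
- `demeaned_slope()`: the association between distance and overlap
  adjusted for dyad and item means, estimated by OLS after a two-way
  within transformation with HC1 robust standard errors. This is a
  deliberate fixed-effects *approximation* to a random-intercept mixed
  model — it preserves the directional test while keeping the
  estimator transparent, and is labelled as such in every output. Its
  slope agrees closely with a random-intercept fit on simulated data
  (tested), but the numbers are not interchangeable with mixed-model
  coefficients.
- `validate_corpus()` ties these together and flags incongruent pairs —
  top distance quartile with overlap ≥ 3, bottom quartile with overlap
  ≤ 1 — as candidates for qualitative inspection, which in practice is
  where systematic failure modes (like mirrored gestures) are found.

## Numerical choices and degenerate inputs

- Local-cost matrices use coordinate-wise differences rather than the
  Gram-matrix identity, so identical frames cost exactly zero — the
  subsequence property depends on it.
- Series shorter than 2 frames are rejected by the aligner (the
  minimum-duration rule upstream prevents this in normal use).
- A torso of (near-)zero length is a degenerate-skeleton error, not a
  division by a tiny number.
- Constant inputs to the correlation, and constant overlap in the slope
  estimator, are explicit errors rather than NaN.
- Frame-rate mismatches between two clips are not resampled — warping
  absorbs time differences and the lengths enter only through the
  `n + m` denominator.

## Problem sizes in the shipped tests

The suite validates the aligner against exhaustive path enumeration
(1000 instances, n, m ≤ 6) and an independent shortest-path formulation
on the alignment DAG (50 pairs, n, m ≤ 30), and runs the end-to-end
recovery on a 200-pair synthetic corpus at the default noise and
occlusion levels — sizes chosen to exercise every branch while keeping
the suite quick on a single core.

## Limitations

The score is holistic: it cannot say *which* feature two gestures share
(handshape and orientation both live in the fingertip channels, and
their contributions mix). Monocular z is heuristic and off by default.
The mirror rule covers one-handed/opposite-hand pairs only; mirrored
two-handed asymmetric gestures are not special-cased. Stroke
segmentation must come from annotation — the package does not detect
gestures. And on real recordings, camera angle, tracking quality and
rater behaviour all push the distance–rating association well below
what the clean synthetic corpus shows.
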