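# gesturedtw

Quantifying how similar two co-speech gestures *look* — their form, not
their meaning — from video-derived pose keypoints.

## The problem

In studies of face-to-face interaction, researchers ask whether speakers
converge on each other's gestures: when two people describe the same
object, do their gestures share handshape, movement, orientation and
position? Traditionally, trained coders rate each gesture pair per
feature, which is slow (months for a few hundred pairs) and categorical.
`gesturedtw` implements an automatic, continuous alternative: a
dissimilarity score computed by dynamic time warping (DTW) over pose
keypoint trajectories, together with the preprocessing that makes the
score meaningful and the statistics that validate it against human
feature coding.

## The method

Inputs are MediaPipe-style keypoint time series (normalized image
coordinates, one row per frame) for each speaker, plus stroke annotations
(start/end seconds, handedness) exported from ELAN.

**Preprocessing** (fixed order): linear interpolation of occlusion gaps →
Gaussian smoothing (σ = 2 frames) → per-frame centering on the mid-torso →
division by torso length (mid-shoulder to mid-hip distance) → x × 16/9
aspect-ratio equalization → y-axis inversion → fingertips re-expressed
relative to the same hand's wrist. The output is invariant to where the
speaker stood and how large they appeared on camera; handshape and
orientation live in the wrist-relative fingertips, position in the wrist.

**Distance.** For each compared hand, open-begin-end *asymmetric* DTW is
run separately on the six hand keypoints (wrist + five fingertips). With
local cost `d(i,j) = ‖q_i − r_j‖` (Euclidean over x, y), the recursion is

    D(i, j) = d(i, j) + min{ D(i−1, j), D(i−1, j−1), D(i−1, j−2) }

with free entry anywhere in the first row (open begin) and the minimum
over the last row as the alignment cost (open end), so imprecise stroke
boundaries are forgiven. Each cumulative cost is normalized by the total
frame count `n + m` and the six keypoint distances are averaged into one
value per hand. Only gesturing hands enter the pair distance; for
one-handed pairs produced with opposite hands, the second gesture is also
mirror-flipped (x negated, hands relabelled) and the lower of the two
distances is adopted. Strokes shorter than 330 ms (ten frames at 30 FPS)
are lengthened with surrounding recording frames before comparison.

**Validation.** Overlap counts (how many of the four features a human
rated similar, 0–4), Spearman rank correlation with exact-permutation,
Monte Carlo or t-approximation p-values, and a dyad/item-demeaned slope
(a fixed-effects approximation to a random-intercept model). A synthetic
dyadic-corpus generator with ground-truth feature similarity makes the
whole chain testable without any recordings.

## Worked example

```r
library(gesturedtw)

# one gesture: arc-shaped right-hand stroke, preprocess, cut the stroke
g    <- render_gesture(gesture_spec(trajectory_kind = "arc", hand = "right"))
clip <- extract_clip(run_pipeline(g$series), g$segment)
clip
#> <gesture_clip> 24 frames (800 ms), right hand(s)

# a small synthetic corpus, end to end
corpus <- generate_corpus(n_pairs = 30, n_dyads = 5, n_items = 6, seed = 7)
res    <- run_all(run_config(seed = 7), corpus = corpus)
res$report
#> <validation_report> 30 pairs
#>   Spearman rho = -0.840 (n = 30), p = 6.664e-09 [t_approximation]
#>   demeaned slope = -0.0341 (SE 0.0031, t = -10.84, p = 1.563e-11, n = 30)
#>   [two-way within OLS approximation to a dyad/item random-intercept model]
#>   handshape    mean distance 0.052 (similar, n=25) vs 0.103 (not, n=5)
#>   movement     mean distance 0.055 (similar, n=23) vs 0.078 (not, n=7)
#>   orientation  mean distance 0.020 (similar, n=17) vs 0.113 (not, n=13)
#>   position     mean distance 0.047 (similar, n=21) vs 0.092 (not, n=9)
#>   3 incongruent pair(s) flagged for qualitative review
```

The negative Spearman rho says the DTW distance drops as the number of
human-rated-similar features rises — the validation the method rests on.
Per-feature rows show mean distance for pairs rated similar vs not on
that feature; flagged incongruent pairs (low distance but low rated
similarity, or the reverse) are the ones worth inspecting by eye.

```r
head(res$distances[, c("pair_id", "pair_distance", "mirror_used", "branch")], 3)
#>   pair_id pair_distance mirror_used          branch
#> 1    p001    0.03539505       FALSE same_hand_right
#> 2    p002    0.02326525       FALSE  same_hand_left
#> 3    p003    0.12604431       FALSE  same_hand_left
```

A command-line front-end with subcommands `simulate`, `preprocess`,
`segment`, `dtw`, `validate` and `run-all` is installed under
`inst/cli/gesturedtw` (`system.file("cli", "gesturedtw", package = "gesturedtw")`).

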