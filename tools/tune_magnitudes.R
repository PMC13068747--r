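# One-off sweep used to settle the default perturbation magnitudes of the
# synthetic generator (PERTURB_DEFAULTS and the handshape/movement swap
# rules). For each single-feature perturbation it compares the pair
# distance against the matched unperturbed pair and reports the
# separation. Not part of the installed package or the test suite.
library(gesturedtw)

separation <- function(feature, magnitudes, n = 40, seed = 1234) {
  set.seed(seed)
  deltas <- vapply(seq_len(n), function(i) {
    base <- gesture_spec(
      trajectory_kind = sample(c("line", "arc", "circle", "zigzag"), 1),
      amplitude = runif(1, 0.12, 0.22), direction = runif(1, 0, 2 * pi),
      anchor = c(runif(1, 0.08, 0.22), runif(1, -0.15, 0.10)),
      handshape = sample(c("open", "fist", "c_shape", "point", "pinch"), 1),
      orientation_angle = runif(1, 0, 2 * pi),
      duration_ms = runif(1, 250, 1100), hand = "right")
    mk <- function(perturb) {
      rp <- render_pair(pair_spec(base, perturb = perturb, noise_sd = 0.004,
                                  occlusion_rate = 0, magnitudes = magnitudes))
      clip <- function(g) extract_clip(run_pipeline(g$series), g$segment)
      pair_distance(clip(rp$a), clip(rp$b))$pair_distance
    }
    mk(feature) - mk(character())
  }, numeric(1))
  c(mean = mean(deltas), sd = sd(deltas), frac_pos = mean(deltas > 0))
}

for (orient in c(pi / 6, pi / 3, pi / 2))
  cat(sprintf("orientation %5.2f rad: %s\n", orient,
              paste(sprintf("%.4f", separation("orientation",
                list(orientation = orient, position = 0.12))), collapse = " ")))
for (pos in c(0.06, 0.12, 0.20))
  cat(sprintf("position    %5.2f    : %s\n", pos,
              paste(sprintf("%.4f", separation("position",
                list(orientation = pi / 2, position = pos))), collapse = " ")))
cat(sprintf("handshape swap      : %s\n",
            paste(sprintf("%.4f", separation("handshape",
              list(orientation = pi / 2, position = 0.12))), collapse = " ")))
cat(sprintf("movement change     : %s\n",
            paste(sprintf("%.4f", separation("movement",
              list(orientation = pi / 2, position = 0.12))), collapse = " ")))
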