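# Synthetic dyadic gesture corpus generator.
#
# Emulates what the real pipeline consumes: two speakers per dyad recorded
# separately, MediaPipe-style normalized coordinates (0-1, y downward,
# heuristic z), a wrist that traces a parametric trajectory while the five
# fingertips ride along as a rotated handshape template, torso landmarks
# with a small postural sway, tracking noise, and occlusion gaps. Each
# generated pair carries ground-truth feature-level similarity: speaker
# B's gesture is speaker A's with zero or more of the four form features
# (handshape, movement, orientation, position) perturbed, which yields
# binary annotations and an overlap count by construction.

HANDSHAPE_TEMPLATES <- local({
  mk <- function(r, ang) cbind(x = r * cospi(ang / 180), y = r * sinpi(ang / 180))
  lapply(list(
    open    = list(r = c(0.80, 1.00, 1.05, 1.00, 0.90), a = c(-50, -15, 5, 25, 45)),
    fist    = list(r = c(0.35, 0.30, 0.30, 0.30, 0.30), a = c(-40, -10, 5, 20, 40)),
    c_shape = list(r = c(0.70, 0.75, 0.75, 0.70, 0.65), a = c(-75, -25, 0, 25, 60)),
    point   = list(r = c(0.40, 1.10, 0.35, 0.30, 0.30), a = c(-45, 0, 12, 26, 42)),
    pinch   = list(r = c(0.75, 0.78, 0.45, 0.40, 0.35), a = c(-8, -3, 15, 30, 45))
  ), function(t) {
    m <- mk(t$r, t$a); rownames(m) <- c("thumb_tip", "index_tip", "middle_tip",
                                        "ring_tip", "pinky_tip"); m
  })
})

TRAJECTORY_KINDS <- c("line", "arc", "circle", "zigzag")

# fingertip offset scale and body geometry, raw image units
HAND_SCALE <- 0.06
BODY <- list(centre = c(0.5, 0.5), shoulder_y = 0.35, hip_y = 0.66,
             shoulder_half = 0.13, hip_half = 0.10,
             rest_wrist = c(0.13, 0.18), z_base = 0.05, sway = 0.004)

# default per-feature perturbation magnitudes (tuned once; see the methods
# vignette for what each does)
PERTURB_DEFAULTS <- list(orientation = pi / 2, position = 0.12)

#' Specify one synthetic gesture
#'
#' @param trajectory_kind wrist path: `"line"`, `"arc"`, `"circle"` or
#'   `"zigzag"`.
#' @param amplitude trajectory extent in raw image units (> 0).
#' @param direction trajectory heading, radians.
#' @param anchor length-2 gesture-space anchor relative to the body
#'   center, in the gesturing side's hand-local frame (x positive =
#'   outward from the midline, y positive = downward in image terms).
#' @param handshape template name; see `names(HANDSHAPE_TEMPLATES)`.
#' @param orientation_angle rotation of the fingertip template, radians.
#' @param duration_ms stroke duration (> 0).
#' @param hand `"left"`, `"right"` or `"both"`.
#' @param fps frame rate, 30 or 50 in the emulated corpora.
#' @return An object of class `gesture_spec`.
#' @export
gesture_spec <- function(trajectory_kind = "line", amplitude = 0.18,
                         direction = 0, anchor = c(0.16, -0.05),
                         handshape = "open", orientation_angle = 0,
                         duration_ms = 800, hand = "right", fps = 30) {
  trajectory_kind <- match.arg(trajectory_kind, TRAJECTORY_KINDS)
  if (!handshape %in% names(HANDSHAPE_TEMPLATES))
    stop(sprintf("unknown handshape template '%s'", handshape))
  stopifnot(amplitude > 0, duration_ms > 0, length(anchor) == 2,
            hand %in% c("left", "right", "both"), fps > 0)
  structure(list(trajectory_kind = trajectory_kind, amplitude = amplitude,
                 direction = direction, anchor = anchor,
                 handshape = handshape,
                 orientation_angle = orientation_angle,
                 duration_ms = duration_ms, hand = hand, fps = fps),
            class = "gesture_spec")
}

# hand-local wrist path at phases p in [0,1]; returns cbind(x, y)
.trajectory_xy <- function(spec, p) {
  a <- spec$amplitude; th <- spec$direction
  rot <- function(x, y) cbind(x = cos(th) * x - sin(th) * y,
                              y = sin(th) * x + cos(th) * y)
  switch(spec$trajectory_kind,
    line = rot(a * (p - 0.5), rep(0, length(p))),
    arc = {
      ang <- pi * p
      rot(0.5 * a * cos(ang), 0.5 * a * sin(ang))
    },
    circle = {
      ang <- 2 * pi * p
      rot(0.5 * a * cos(ang), 0.5 * a * sin(ang))
    },
    zigzag = {
      tri <- function(u) 2 * abs(2 * (u %% 1) - 1) - 1    # triangle wave
      rot(a * (p - 0.5), 0.30 * a * tri(3 * p))
    })
}

# rotated, side-adjusted fingertip offsets (5 x 2); side flips x
.template_offsets <- function(spec, side) {
  m <- HANDSHAPE_TEMPLATES[[spec$handshape]] * HAND_SCALE
  th <- spec$orientation_angle
  r <- cbind(cos(th) * m[, 1] - sin(th) * m[, 2],
             sin(th) * m[, 1] + cos(th) * m[, 2])
  if (side == "right") r[, 1] <- -r[, 1]   # mirror about the body midline
  r
}

# map a hand-local (x outward, y down) point to image coords for a side
.place <- function(side, xy) {
  sgn <- if (side == "left") 1 else -1
  cbind(BODY$centre[1] + sgn * xy[, 1], BODY$centre[2] + xy[, 2])
}

#' Render a synthetic gesture recording
#'
#' Produces a full skeleton time series in raw MediaPipe-style units: a
#' lead-in and tail with the gesturing hand holding the stroke endpoints,
#' the stroke itself, a resting opposite hand, a gently swaying torso,
#' Gaussian tracking noise and optional occlusion gaps. Deterministic for
#' a given RNG state.
#'
#' @param spec a [gesture_spec].
#' @param lead_s,tail_s seconds of hold before/after the stroke.
#' @param noise_sd coordinate noise standard deviation (raw units).
#' @param occlusion_rate per-landmark probability of one occlusion gap.
#' @return A list with `series` (a [skeleton_ts]) and `segment` (the
#'   stroke [gesture_segment] with dyad/speaker/trial left blank).
#' @export
render_gesture <- function(spec, lead_s = 0.4, tail_s = 0.4,
                           noise_sd = 0, occlusion_rate = 0) {
  fps <- spec$fps
  n_stroke <- max(2L, round(spec$duration_ms / 1000 * fps))
  n_lead <- round(lead_s * fps); n_tail <- round(tail_s * fps)
  n <- n_lead + n_stroke + n_tail
  p <- c(rep(0, n_lead), seq(0, 1, length.out = n_stroke), rep(1, n_tail))
  arr <- array(NA_real_, c(n, length(CORE_LANDMARKS), 3L),
               dimnames = list(NULL, CORE_LANDMARKS, AXES))
  sway <- BODY$sway * sin(2 * pi * seq_len(n) / (4 * fps))
  torso_x <- c(left_shoulder = BODY$shoulder_half,
               right_shoulder = -BODY$shoulder_half,
               left_hip = BODY$hip_half, right_hip = -BODY$hip_half)
  torso_y <- c(left_shoulder = BODY$shoulder_y, right_shoulder = BODY$shoulder_y,
               left_hip = BODY$hip_y, right_hip = BODY$hip_y)
  for (lm in TORSO_LANDMARKS) {
    arr[, lm, "x"] <- BODY$centre[1] + torso_x[[lm]] + sway
    arr[, lm, "y"] <- torso_y[[lm]] + 0.5 * sway
    arr[, lm, "z"] <- BODY$z_base
  }
  gest_sides <- if (spec$hand == "both") c("left", "right") else spec$hand
  for (side in c("left", "right")) {
    wname <- paste0(side, "_wrist")
    if (side %in% gest_sides) {
      local_xy <- sweep(.trajectory_xy(spec, p), 2, spec$anchor, "+")
      w <- .place(side, local_xy)
      off <- .template_offsets(spec, side)
    } else {
      w <- .place(side, matrix(rep(BODY$rest_wrist, each = n), ncol = 2))
      rest <- spec; rest$handshape <- "fist"; rest$orientation_angle <- 0
      off <- .template_offsets(rest, side)
    }
    arr[, wname, "x"] <- w[, 1] + sway
    arr[, wname, "y"] <- w[, 2]
    arr[, wname, "z"] <- BODY$z_base + 0.01
    for (tip in rownames(off)) {
      tname <- paste0(side, "_", tip)
      arr[, tname, "x"] <- w[, 1] + off[tip, 1] + sway
      arr[, tname, "y"] <- w[, 2] + off[tip, 2]
      arr[, tname, "z"] <- BODY$z_base + 0.02
    }
  }
  if (noise_sd > 0)
    arr <- arr + array(stats::rnorm(length(arr), 0, noise_sd), dim(arr))
  if (occlusion_rate > 0) arr <- .inject_occlusions(arr, occlusion_rate)
  series <- skeleton_ts(arr, fps = fps)
  segment <- gesture_segment("", "", "", t_start = n_lead / fps,
                             t_end = (n_lead + n_stroke) / fps,
                             handedness = spec$hand)
  list(series = series, segment = segment)
}

# one gap per sampled landmark, at most 40% of frames, never the whole track
.inject_occlusions <- function(arr, rate) {
  n <- dim(arr)[1]
  for (lm_i in seq_len(dim(arr)[2])) {
    if (stats::runif(1) >= rate) next
    len <- max(1L, min(n - 1L, stats::rgeom(1, 0.25) + 1L, floor(0.4 * n)))
    start <- sample.int(n - len + 1L, 1L)
    arr[start:(start + len - 1L), lm_i, ] <- NA_real_
  }
  arr
}

#' Specify a synthetic gesture pair
#'
#' @param base speaker A's [gesture_spec].
#' @param perturb character vector naming the features of speaker B's
#'   gesture to perturb, a subset of
#'   `c("handshape", "movement", "orientation", "position")`.
#' @param mirror if `TRUE` (one-handed `base` only), speaker B gestures
#'   with the opposite hand as a mirror image.
#' @param noise_sd,occlusion_rate rendering noise parameters.
#' @param duration_factor B's stroke duration relative to A's.
#' @param magnitudes perturbation magnitudes (`orientation` radians,
#'   `position` raw units).
#' @return An object of class `pair_spec`.
#' @export
pair_spec <- function(base, perturb = character(), mirror = FALSE,
                      noise_sd = 0.004, occlusion_rate = 0.05,
                      duration_factor = 1,
                      magnitudes = PERTURB_DEFAULTS) {
  stopifnot(inherits(base, "gesture_spec"),
            all(perturb %in% FEATURES),
            occlusion_rate >= 0, occlusion_rate < 1)
  if (mirror && base$hand == "both")
    stop("mirrored pairs require a one-handed base gesture")
  structure(list(base = base, perturb = perturb, mirror = mirror,
                 noise_sd = noise_sd, occlusion_rate = occlusion_rate,
                 duration_factor = duration_factor, magnitudes = magnitudes),
            class = "pair_spec")
}

# derive speaker B's spec from a pair_spec (consumes RNG for the
# perturbation directions)
.derive_b_spec <- function(ps) {
  b <- ps$base
  if ("handshape" %in% ps$perturb) {
    others <- setdiff(names(HANDSHAPE_TEMPLATES), b$handshape)
    b$handshape <- sample(others, 1L)
  }
  if ("movement" %in% ps$perturb) {
    others <- setdiff(TRAJECTORY_KINDS, b$trajectory_kind)
    b$trajectory_kind <- sample(others, 1L)
    b$direction <- b$direction + pi      # and reverse the heading
  }
  if ("orientation" %in% ps$perturb)
    b$orientation_angle <- b$orientation_angle +
      sample(c(-1, 1), 1L) * ps$magnitudes$orientation
  if ("position" %in% ps$perturb) {
    ang <- stats::runif(1, 0, 2 * pi)
    b$anchor <- b$anchor + ps$magnitudes$position * c(cos(ang), sin(ang))
  }
  b$duration_ms <- b$duration_ms * ps$duration_factor
  if (ps$mirror)
    b$hand <- switch(b$hand, left = "right", right = "left", b$hand)
  b
}

#' Render a synthetic gesture pair with ground-truth similarity
#'
#' Speaker B's gesture is speaker A's with the flagged features perturbed
#' (handshape: template swap; movement: trajectory kind change plus
#' heading reversal; orientation: template rotation; position: anchor
#' shift). The annotation marks unperturbed features as similar (1) and
#' perturbed ones as not (0); `handedness_match` records whether the two
#' speakers used the same hand(s).
#'
#' @param ps a [pair_spec].
#' @return A list with `a` and `b` (each a `list(series, segment)` from
#'   [render_gesture()]) and `annotation` (a [similarity_annotation]).
#' @export
render_pair <- function(ps) {
  stopifnot(inherits(ps, "pair_spec"))
  spec_b <- .derive_b_spec(ps)
  a <- render_gesture(ps$base, noise_sd = ps$noise_sd,
                      occlusion_rate = ps$occlusion_rate)
  b <- render_gesture(spec_b, noise_sd = ps$noise_sd,
                      occlusion_rate = ps$occlusion_rate)
  r <- as.list(as.integer(!FEATURES %in% ps$perturb))
  names(r) <- FEATURES
  ann <- similarity_annotation(r$handshape, r$movement, r$orientation,
                               r$position,
                               handedness_match =
                                 as.integer(ps$base$hand == spec_b$hand),
                               scale = "binary")
  list(a = a, b = b, annotation = ann, spec_b = spec_b)
}

# per-pair count of perturbed features; expectation ~1.02 of 4, so the
# share of feature ratings marked similar is ~0.745, matching the
# annotated corpora this generator emulates
PERTURB_COUNT_PROBS <- c(`0` = 0.40, `1` = 0.35, `2` = 0.13,
                         `3` = 0.07, `4` = 0.05)

#' Generate a synthetic dyadic gesture corpus
#'
#' Draws `n_pairs` referentially aligned gesture pairs spread over
#' `n_dyads` dyads and `n_items` items. Each pair gets a random base
#' gesture; the number of perturbed features is drawn so that roughly
#' three quarters of all feature ratings come out "similar", and a share
#' of one-handed pairs is rendered mirrored (speaker B using the opposite
#' hand). Fully reproducible from `seed` (R's default Mersenne-Twister
#' RNG).
#'
#' @param n_pairs number of gesture pairs.
#' @param n_dyads,n_items grouping structure.
#' @param seed integer RNG seed.
#' @param fps frame rate of the emulated recordings (30 or 50).
#' @param noise_sd,occlusion_rate rendering noise parameters.
#' @param p_mirror probability that a one-handed pair is mirrored.
#' @return A list of class `synthetic_corpus`: `recordings` (named list
#'   of [skeleton_ts], two per pair), `segments` (named list of
#'   [gesture_segment]), `pairs` (data frame: `pair_id`, `clip_a`,
#'   `clip_b`, `dyad_id`, `trial_id`, `mirrored`), `annotations` (data
#'   frame with `pair_id` and the four feature columns).
#' @export
generate_corpus <- function(n_pairs = 200, n_dyads = 10, n_items = 16,
                            seed = 1, fps = 30, noise_sd = 0.004,
                            occlusion_rate = 0.05, p_mirror = 0.15) {
  stopifnot(n_pairs >= 1, n_dyads >= 1, n_items >= 1)
  set.seed(as.integer(seed))
  recordings <- list(); segments <- list()
  pairs <- vector("list", n_pairs); anns <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pid <- sprintf("p%03d", i)
    dyad <- sprintf("d%02d", (i - 1L) %% n_dyads + 1L)
    item <- sprintf("i%02d", (i - 1L) %% n_items + 1L)
    base <- gesture_spec(
      trajectory_kind = sample(TRAJECTORY_KINDS, 1L),
      amplitude = stats::runif(1, 0.12, 0.22),
      direction = stats::runif(1, 0, 2 * pi),
      anchor = c(stats::runif(1, 0.08, 0.22), stats::runif(1, -0.15, 0.10)),
      handshape = sample(names(HANDSHAPE_TEMPLATES), 1L),
      orientation_angle = stats::runif(1, 0, 2 * pi),
      duration_ms = stats::runif(1, 250, 1100),
      hand = sample(c("left", "right", "both"), 1L, prob = c(.35, .35, .30)),
      fps = fps)
    k <- sample(0:4, 1L, prob = PERTURB_COUNT_PROBS)
    perturb <- if (k > 0) sample(FEATURES, k) else character()
    mirror <- base$hand != "both" && stats::runif(1) < p_mirror
    ps <- pair_spec(base, perturb = perturb, mirror = mirror,
                    noise_sd = noise_sd, occlusion_rate = occlusion_rate,
                    duration_factor = stats::runif(1, 0.9, 1.15))
    rp <- render_pair(ps)
    ka <- paste0(pid, "_A"); kb <- paste0(pid, "_B")
    rp$a$series$speaker_id <- "A"; rp$b$series$speaker_id <- "B"
    rp$a$series$recording_id <- ka; rp$b$series$recording_id <- kb
    rp$a$segment$dyad_id <- dyad; rp$b$segment$dyad_id <- dyad
    rp$a$segment$speaker_id <- "A"; rp$b$segment$speaker_id <- "B"
    rp$a$segment$trial_id <- item; rp$b$segment$trial_id <- item
    recordings[[ka]] <- rp$a$series; recordings[[kb]] <- rp$b$series
    segments[[ka]] <- rp$a$segment; segments[[kb]] <- rp$b$segment
    pairs[[i]] <- data.frame(pair_id = pid, clip_a = ka, clip_b = kb,
                             dyad_id = dyad, trial_id = item,
                             mirrored = mirror, stringsAsFactors = FALSE)
    anns[[i]] <- data.frame(pair_id = pid,
                            handshape = rp$annotation$ratings[["handshape"]],
                            movement = rp$annotation$ratings[["movement"]],
                            orientation = rp$annotation$ratings[["orientation"]],
                            position = rp$annotation$ratings[["position"]],
                            handedness_match = rp$annotation$handedness_match,
                            stringsAsFactors = FALSE)
  }
  structure(list(recordings = recordings, segments = segments,
                 pairs = do.call(rbind, pairs),
                 annotations = do.call(rbind, anns),
                 fps = fps, seed = seed),
            class = "synthetic_corpus")
}

#' Write a synthetic corpus to plain-text files
#'
#' Emits one keypoint CSV per recording, a segment TSV, a pair CSV and an
#' annotation CSV under `dir`, in the dialects the readers in this
#' package expect.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(corpus$recordings))
    write_keypoint_timeseries(corpus$recordings[[key]],
                              file.path(dir, paste0(key, ".csv")))
  segs <- corpus$segments
  df <- data.frame(
    dyad = vapply(segs, `[[`, "", "dyad_id"),
    speaker = vapply(segs, `[[`, "", "speaker_id"),
    trial = vapply(segs, `[[`, "", "trial_id"),
    t_start = vapply(segs, `[[`, 0, "t_start"),
    t_end = vapply(segs, `[[`, 0, "t_end"),
    handedness = vapply(segs, `[[`, "", "handedness"),
    recording = names(segs))
  .write_csv_precise(df, file.path(dir, "segments.tsv"), sep = "\t")
  .write_csv_precise(corpus$pairs, file.path(dir, "pairs.csv"))
  .write_csv_precise(corpus$annotations, file.path(dir, "annotations.csv"))
  invisible(dir)
}
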