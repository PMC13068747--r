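# Preprocessing chain for normalized pose keypoints, applied in a fixed
# order: interpolate -> smooth -> center on mid-torso -> scale by torso
# length -> aspect-ratio adjust x -> invert y -> wrist-relative fingertips.
# The chain makes two gestures comparable regardless of where a speaker
# stood, how large they appeared on camera, and where their hand happened
# to be in gesture space.

#' Preprocessing configuration
#'
#' @param sigma Gaussian smoothing standard deviation in frames
#'   (default 2; 0 disables smoothing).
#' @param aspect_ratio multiplier applied to x to equalize x/y units for
#'   16:9 video (default `16/9`).
#' @param use_z include the (monocular, heuristic) z coordinate in the
#'   distance computation (default `FALSE`; x/y only).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sigma = 2, aspect_ratio = 16 / 9,
                              use_z = FALSE) {
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  if (!is.numeric(aspect_ratio) || aspect_ratio <= 0)
    stop("`aspect_ratio` must be > 0")
  structure(list(sigma = sigma, aspect_ratio = aspect_ratio,
                 use_z = isTRUE(use_z)),
            class = "preprocess_config")
}

#' Fill occlusion gaps by linear interpolation
#'
#' Pose trackers lose occluded keypoints, leaving NA runs. Interior gaps
#' are filled linearly between the flanking observations, so
#' `c(1, 2, NA, NA, 5)` becomes `c(1, 2, 3, 4, 5)`; leading and trailing
#' gaps copy the nearest observed value.
#'
#' @param series a [skeleton_ts].
#' @return A [skeleton_ts] without missing values.
#' @export
interpolate_missing <- function(series) {
  stopifnot(inherits(series, "skeleton_ts"))
  out <- series
  nf <- n_frames(series)
  for (lm in landmark_names(series))
    for (ax in AXES) {
      v <- series$coords[, lm, ax]
      if (!anyNA(v)) next
      obs <- which(!is.na(v))
      if (length(obs) == 0L)
        stop(sprintf("landmark '%s' axis %s has no observed values", lm, ax))
      out$coords[, lm, ax] <- .interp_vector(v, obs, nf)
    }
  out
}

.interp_vector <- function(v, obs, nf) {
  if (length(obs) == 1L) return(rep(v[obs], nf))
  # rule = 2 extends leading/trailing gaps with the nearest observation
  stats::approx(x = obs, y = v[obs], xout = seq_len(nf), rule = 2)$y
}

#' Gaussian smoothing of keypoint trajectories
#'
#' Convolves every landmark-coordinate track with a discretized Gaussian
#' kernel (truncated at 4 sigma, renormalized to sum to 1) to damp
#' frame-to-frame tracking jitter. Edges are handled by reflection, so a
#' constant track stays constant. `sigma = 0` returns the input unchanged.
#'
#' @param series a [skeleton_ts] with no missing values (interpolate first).
#' @param sigma kernel standard deviation in frames.
#' @return A smoothed [skeleton_ts].
#' @export
smooth_series <- function(series, sigma = 2) {
  stopifnot(inherits(series, "skeleton_ts"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a nonnegative scalar")
  if (anyNA(series$coords))
    stop("smoothing requires a gap-free series; run interpolate_missing() first")
  if (sigma == 0) return(series)
  k <- gaussian_kernel(sigma)
  out <- series
  for (lm in landmark_names(series))
    for (ax in AXES)
      out$coords[, lm, ax] <- .convolve_reflect(series$coords[, lm, ax], k)
  out
}

#' @rdname smooth_series
#' @export
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(floor(4 * sigma + 0.5)))
  t <- (-r):r
  k <- exp(-0.5 * (t / sigma)^2)
  k / sum(k)
}

.convolve_reflect <- function(v, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(v)
  # reflect-about-edge padding (d c b a | a b c d | d c b a), with period
  # 2n so it stays valid even when the kernel radius exceeds the series
  i <- (1L - r):(n + r)
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < n, j + 1L, 2L * n - j)
  padded <- v[j]
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Center keypoints on the mid-torso
#'
#' Subtracts the per-frame mid-torso (mean of the two shoulders and two
#' hips) from every landmark, so the body center sits at the origin in
#' every frame and standing position drops out of the distance. Also
#' computes the torso-length size scale (median across frames of the 3D
#' mid-shoulder to mid-hip distance) used by [normalize_size()].
#'
#' @param series a [skeleton_ts] containing the four torso landmarks.
#' @return A list with elements `series` (centered [skeleton_ts]) and
#'   `info` (list with per-frame `mid_torso` matrix and scalar
#'   `torso_length`).
#' @export
normalize_position <- function(series) {
  stopifnot(inherits(series, "skeleton_ts"))
  miss <- setdiff(TORSO_LANDMARKS, landmark_names(series))
  if (length(miss))
    stop(sprintf("torso landmark(s) missing: %s", paste(miss, collapse = ", ")))
  tor <- series$coords[, TORSO_LANDMARKS, , drop = FALSE]
  if (anyNA(tor))
    stop("torso landmarks contain missing values; interpolate first")
  mid_torso <- apply(tor, c(1, 3), mean)          # frames x 3
  mid_sh <- (series$coords[, "left_shoulder", ] +
             series$coords[, "right_shoulder", ]) / 2
  mid_hip <- (series$coords[, "left_hip", ] +
              series$coords[, "right_hip", ]) / 2
  if (n_frames(series) == 1L) {
    mid_sh <- matrix(mid_sh, 1); mid_hip <- matrix(mid_hip, 1)
  }
  torso_length <- stats::median(sqrt(rowSums((mid_sh - mid_hip)^2)))
  out <- series
  for (ax_i in 1:3)
    out$coords[, , ax_i] <- series$coords[, , ax_i] - mid_torso[, ax_i]
  list(series = out,
       info = list(mid_torso = mid_torso, torso_length = torso_length))
}

#' Scale keypoints by torso length
#'
#' Divides every coordinate by the torso length (mid-shoulder to mid-hip
#' distance) so that body size and camera proximity drop out: after the
#' operation the torso measures one unit.
#'
#' @param series a position-normalized [skeleton_ts].
#' @param info the `info` element returned by [normalize_position()].
#' @return A size-normalized [skeleton_ts].
#' @export
normalize_size <- function(series, info) {
  stopifnot(inherits(series, "skeleton_ts"))
  tl <- info$torso_length
  if (!is.finite(tl) || tl <= 1e-6)
    stop("degenerate skeleton: torso length is zero (or nearly so)")
  out <- series
  out$coords <- series$coords / tl
  out
}

#' Adjust the x axis for the video aspect ratio
#'
#' Normalized image coordinates run 0-1 on both axes even though 16:9
#' video is 1.78 times wider than tall, so equal physical displacements
#' map to unequal coordinate displacements. Multiplying x by the aspect
#' ratio equalizes the units: a 0.1 horizontal displacement becomes
#' 0.178, matching the same physical displacement expressed vertically.
#'
#' @param series a [skeleton_ts].
#' @param aspect_ratio width/height multiplier (default `16/9`).
#' @return A [skeleton_ts] with x scaled; y and z untouched.
#' @export
adjust_aspect <- function(series, aspect_ratio = 16 / 9) {
  stopifnot(inherits(series, "skeleton_ts"))
  if (!is.numeric(aspect_ratio) || aspect_ratio <= 0)
    stop("`aspect_ratio` must be > 0")
  out <- series
  out$coords[, , "x"] <- series$coords[, , "x"] * aspect_ratio
  out
}

#' Invert the y axis
#'
#' Image coordinates grow downward; flipping the sign makes larger y mean
#' higher in space, which reads naturally after mid-torso centering.
#' Applying the operation twice restores the input.
#'
#' @param series a [skeleton_ts].
#' @return A [skeleton_ts] with `y <- -y`.
#' @export
invert_y <- function(series) {
  stopifnot(inherits(series, "skeleton_ts"))
  out <- series
  out$coords[, , "y"] <- -series$coords[, , "y"]
  out
}

#' Express fingertips relative to the same hand's wrist
#'
#' Replaces each fingertip coordinate by fingertip minus wrist, per frame
#' and per hand. The resulting relative finger positions encode handshape
#' and hand orientation while discarding where the hand is; hand position
#' stays encoded in the (untouched) wrist keypoints.
#'
#' @param series a [skeleton_ts] with wrists and fingertips.
#' @return A [skeleton_ts] with wrist-relative fingertip coordinates.
#' @export
relative_fingertips <- function(series) {
  stopifnot(inherits(series, "skeleton_ts"))
  out <- series
  tips <- setdiff(HAND_KEYPOINTS, "wrist")
  for (side in c("left", "right")) {
    wrist <- paste0(side, "_wrist")
    if (!wrist %in% landmark_names(series))
      stop(sprintf("landmark '%s' missing", wrist))
    w <- series$coords[, wrist, , drop = FALSE]
    for (tip in paste0(side, "_", tips)) {
      if (!tip %in% landmark_names(series))
        stop(sprintf("landmark '%s' missing", tip))
      out$coords[, tip, ] <- series$coords[, tip, ] - w[, 1, ]
    }
  }
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in this fixed order: [interpolate_missing()],
#' [smooth_series()], [normalize_position()], [normalize_size()],
#' [adjust_aspect()], [invert_y()], [relative_fingertips()]. The output is
#' invariant to global translation and global rescaling of the input.
#'
#' @param series a raw [skeleton_ts].
#' @param config a [preprocess_config].
#' @return A preprocessed [skeleton_ts]; the normalization info is
#'   attached as attribute `"norm_info"`.
#' @export
run_pipeline <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "skeleton_ts"),
            inherits(config, "preprocess_config"))
  s <- interpolate_missing(series)
  s <- smooth_series(s, config$sigma)
  np <- normalize_position(s)
  s <- normalize_size(np$series, np$info)
  s <- adjust_aspect(s, config$aspect_ratio)
  s <- invert_y(s)
  s <- relative_fingertips(s)
  attr(s, "norm_info") <- np$info
  s
}
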