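#' @keywords internal
"_PACKAGE"

#' Landmark sets
#'
#' The pipeline tracks, per speaker, the wrist and the five fingertips of
#' each hand plus four torso landmarks (shoulders and hips). Torso landmarks
#' anchor the position/size normalization; the six hand keypoints (wrist +
#' fingertips) are the ones entering the distance computation.
#'
#' @format Character vectors of landmark identifiers.
#' @name landmarks
NULL

#' @rdname landmarks
#' @export
HAND_KEYPOINTS <- c("wrist", "thumb_tip", "index_tip", "middle_tip",
                    "ring_tip", "pinky_tip")

#' @rdname landmarks
#' @export
TORSO_LANDMARKS <- c("left_shoulder", "right_shoulder",
                     "left_hip", "right_hip")

#' @rdname landmarks
#' @export
CORE_LANDMARKS <- c(paste0("left_", HAND_KEYPOINTS),
                    paste0("right_", HAND_KEYPOINTS),
                    TORSO_LANDMARKS)

AXES <- c("x", "y", "z")

#' Construct a skeleton time series
#'
#' A `skeleton_ts` holds per-frame 3D coordinates for a fixed landmark set,
#' in MediaPipe-style normalized image units (each axis nominally 0-1, y
#' increasing downward in the raw input, z a monocular depth heuristic).
#' Missing coordinates (occlusions) are `NA`.
#'
#' @param coords numeric array `[frames, landmarks, 3]`, dimnames on the
#'   second margin naming landmarks and on the third `c("x","y","z")`, or a
#'   wide data frame with `<landmark>_x|_y|_z` columns.
#' @param fps frames per second, a positive scalar.
#' @param landmarks landmark names; defaults to the array dimnames.
#' @param speaker_id,recording_id opaque labels carried through the pipeline.
#' @return An object of class `skeleton_ts`.
#' @examples
#' arr <- array(0, c(5, length(CORE_LANDMARKS), 3),
#'              dimnames = list(NULL, CORE_LANDMARKS, c("x", "y", "z")))
#' s <- skeleton_ts(arr, fps = 30)
#' n_frames(s)
#' @export
skeleton_ts <- function(coords, fps, landmarks = NULL,
                        speaker_id = NA_character_,
                        recording_id = NA_character_) {
  if (is.data.frame(coords)) coords <- .wide_df_to_array(coords, landmarks)
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.null(landmarks)) dimnames(coords)[[2]] <- landmarks
  if (is.null(dimnames(coords)[[2]]))
    stop("landmark names are required (array dimnames or `landmarks`)")
  dimnames(coords)[[3]] <- AXES
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a positive finite scalar")
  if (dim(coords)[1] < 1L) stop("a skeleton time series needs at least one frame")
  if (any(is.infinite(coords)))
    stop("coordinates must be finite or NA, never infinite")
  structure(
    list(coords = coords, fps = as.numeric(fps),
         speaker_id = speaker_id, recording_id = recording_id),
    class = "skeleton_ts")
}

.wide_df_to_array <- function(df, landmarks = NULL) {
  cn <- names(df)
  if (is.null(landmarks)) {
    hit <- grepl("_(x|y|z)$", cn)
    landmarks <- unique(sub("_(x|y|z)$", "", cn[hit]))
  }
  arr <- array(NA_real_, c(nrow(df), length(landmarks), 3L),
               dimnames = list(NULL, landmarks, AXES))
  for (lm in landmarks)
    for (ax in AXES) {
      col <- paste0(lm, "_", ax)
      if (col %in% cn) arr[, lm, ax] <- as.numeric(df[[col]])
    }
  arr
}

#' @export
print.skeleton_ts <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<skeleton_ts> %d frames x %d landmarks @ %g FPS (%.2f s)\n",
              d[1], d[2], x$fps, d[1] / x$fps))
  na <- sum(is.na(x$coords))
  if (na > 0)
    cat(sprintf("  %d missing coordinate values (%.1f%%)\n",
                na, 100 * na / length(x$coords)))
  invisible(x)
}

#' @rdname skeleton_ts
#' @param x a `skeleton_ts`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname skeleton_ts
#' @export
landmark_names <- function(x) dimnames(x$coords)[[2]]

#' Subset frames of a skeleton time series
#'
#' @param x a `skeleton_ts`.
#' @param frames integer frame indices (1-based).
#' @return A `skeleton_ts` restricted to `frames`.
#' @export
subset_frames <- function(x, frames) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(x)))
  out <- x
  out$coords <- x$coords[frames, , , drop = FALSE]
  out
}

#' Extract one landmark's trajectory
#'
#' @param x a `skeleton_ts`.
#' @param landmark landmark name.
#' @param axes which coordinate axes to return (columns).
#' @return Numeric matrix `[frames, length(axes)]`.
#' @export
trajectory <- function(x, landmark, axes = c("x", "y")) {
  if (!landmark %in% landmark_names(x))
    stop(sprintf("landmark '%s' not present in series", landmark))
  m <- x$coords[, landmark, axes, drop = FALSE]
  dim(m) <- c(dim(m)[1], dim(m)[3])   # middle margin has length 1
  colnames(m) <- axes
  m
}

#' Gesture segment annotations
#'
#' One manually annotated gesture stroke: which speaker of which dyad,
#' which trial/referent, the stroke window in seconds, and handedness.
#'
#' @param dyad_id,speaker_id,trial_id labels.
#' @param t_start,t_end stroke window in seconds, `t_end > t_start`.
#' @param handedness one of `"left"`, `"right"`, `"both"`.
#' @return An object of class `gesture_segment`.
#' @export
gesture_segment <- function(dyad_id, speaker_id, trial_id,
                            t_start, t_end, handedness) {
  handedness <- as.character(handedness)
  if (!handedness %in% c("left", "right", "both"))
    stop(sprintf("unknown handedness token '%s'", handedness))
  t_start <- as.numeric(t_start); t_end <- as.numeric(t_end)
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start)
    stop("t_end must be strictly greater than t_start")
  structure(
    list(dyad_id = as.character(dyad_id),
         speaker_id = as.character(speaker_id),
         trial_id = as.character(trial_id),
         t_start = t_start, t_end = t_end, handedness = handedness),
    class = "gesture_segment")
}

#' @export
print.gesture_segment <- function(x, ...) {
  cat(sprintf("<gesture_segment> dyad %s speaker %s trial %s [%.3f, %.3f)s %s\n",
              x$dyad_id, x$speaker_id, x$trial_id,
              x$t_start, x$t_end, x$handedness))
  invisible(x)
}

#' Per-feature similarity annotation
#'
#' Human similarity ratings for one referentially aligned gesture pair on
#' the four form features handshape, movement, orientation and position,
#' either binary (0 = not similar, 1 = similar) or ordinal on 0-5.
#' Handedness match is carried separately because the distance computation
#' already conditions on gesturing hands.
#'
#' @param handshape,movement,orientation,position feature ratings.
#' @param handedness_match optional binary flag (same hands used).
#' @param scale `"binary"` or `"ordinal6"`.
#' @return An object of class `similarity_annotation`.
#' @export
similarity_annotation <- function(handshape, movement, orientation, position,
                                  handedness_match = NA,
                                  scale = c("binary", "ordinal6")) {
  scale <- match.arg(scale)
  r <- c(handshape = handshape, movement = movement,
         orientation = orientation, position = position)
  ok <- if (scale == "binary") all(r %in% c(0, 1)) else all(r %in% 0:5)
  if (!ok)
    stop(sprintf("ratings out of range for scale '%s'", scale))
  structure(list(ratings = r, handedness_match = handedness_match,
                 scale = scale),
            class = "similarity_annotation")
}
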