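# Stroke extraction. Annotated stroke times (seconds) map to frames with a
# half-open [round(t_start*fps), round(t_end*fps)) window, 0-based. Very
# short strokes give unreliable alignment distances, so clips below a
# minimum duration (330 ms by default; ten frames at 30 FPS, seventeen at
# 50 FPS) are lengthened with real surrounding frames from the recording,
# split as evenly as possible before and after the stroke.

#' Minimum clip length in frames
#'
#' @param fps frames per second.
#' @param min_ms minimum duration in milliseconds (default 330).
#' @return Integer minimum frame count, `ceiling(min_ms/1000 * fps)`.
#' @examples
#' min_clip_frames(30)  # 10
#' min_clip_frames(50)  # 17
#' @export
min_clip_frames <- function(fps, min_ms = 330) {
  stopifnot(fps > 0, min_ms > 0)
  as.integer(ceiling(min_ms / 1000 * fps))
}

#' Extract a gesture clip from a recording
#'
#' Cuts the stroke window out of the full recording and, if the result is
#' shorter than the minimum duration, pads it with surrounding frames via
#' [pad_to_minimum()].
#'
#' @param series the full-recording [skeleton_ts] (preprocessed or raw).
#' @param segment a [gesture_segment].
#' @param min_ms minimum clip duration in milliseconds; `0` disables
#'   padding.
#' @return A `gesture_clip`: list with `segment`, `series` (the windowed
#'   [skeleton_ts]), `n_frames`, `padded`, `pad_before`, `pad_after`, and
#'   the frame window `first_frame`/`last_frame` (1-based, inclusive).
#' @export
extract_clip <- function(series, segment, min_ms = 330) {
  stopifnot(inherits(series, "skeleton_ts"),
            inherits(segment, "gesture_segment"))
  fps <- series$fps
  f0 <- round(segment$t_start * fps)        # 0-based half-open [f0, f1)
  f1 <- round(segment$t_end * fps)
  nf <- n_frames(series)
  if (f0 < 0 || f1 > nf)
    stop(sprintf("stroke window [%g, %g)s maps to frames [%d, %d) outside the %d-frame recording",
                 segment$t_start, segment$t_end, f0, f1, nf))
  if (f1 <= f0)
    stop("stroke window rounds to zero frames; check times and fps")
  clip <- structure(
    list(segment = segment,
         series = subset_frames(series, (f0 + 1L):f1),
         n_frames = f1 - f0,
         padded = FALSE, pad_before = 0L, pad_after = 0L,
         first_frame = f0 + 1L, last_frame = f1),
    class = "gesture_clip")
  if (min_ms > 0) clip <- pad_to_minimum(clip, series, min_ms) else clip
}

#' Lengthen a short clip to the minimum duration
#'
#' Clips shorter than `min_ms` are extended with frames that exist in the
#' source recording, split as evenly as possible before and after the
#' stroke; an odd deficit puts the extra frame after the stroke, and when
#' one side runs into a recording boundary the remainder is taken from the
#' other side.
#'
#' @param clip a `gesture_clip` from [extract_clip()].
#' @param full_series the recording the clip was cut from.
#' @param min_ms minimum duration in milliseconds.
#' @return The (possibly padded) `gesture_clip`.
#' @export
pad_to_minimum <- function(clip, full_series, min_ms = 330) {
  stopifnot(inherits(clip, "gesture_clip"),
            inherits(full_series, "skeleton_ts"))
  need <- min_clip_frames(full_series$fps, min_ms)
  if (clip$n_frames >= need) return(clip)
  nf <- n_frames(full_series)
  if (nf < need)
    stop(sprintf("recording has %d frames, fewer than the %d-frame minimum",
                 nf, need))
  deficit <- need - clip$n_frames
  before <- deficit %/% 2L
  after <- deficit - before                  # odd deficit: extra frame after
  avail_before <- clip$first_frame - 1L
  avail_after <- nf - clip$last_frame
  if (before > avail_before) {
    after <- after + (before - avail_before); before <- avail_before
  }
  if (after > avail_after) {
    extra <- after - avail_after
    after <- avail_after
    before <- min(before + extra, avail_before)
  }
  first <- clip$first_frame - before
  last <- clip$last_frame + after
  clip$series <- subset_frames(full_series, first:last)
  clip$n_frames <- last - first + 1L
  clip$padded <- TRUE
  clip$pad_before <- before
  clip$pad_after <- after
  clip$first_frame <- first
  clip$last_frame <- last
  clip
}

#' @export
print.gesture_clip <- function(x, ...) {
  cat(sprintf("<gesture_clip> %d frames (%s)%s, %s hand(s)\n",
              x$n_frames,
              sprintf("%.0f ms", 1000 * x$n_frames / x$series$fps),
              if (x$padded)
                sprintf(", padded +%d/+%d", x$pad_before, x$pad_after)
              else "",
              x$segment$handedness))
  invisible(x)
}
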