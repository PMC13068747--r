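# File formats: keypoint CSVs are wide (one row per frame, columns
# <landmark>_x|_y|_z, comma-separated, UTF-8), matching MediaPipe export
# scripts. Segment tables are tab-separated ELAN exports. Empty cells are
# missing coordinates and must survive round-trips as NA, never as zeros.

#' Read a keypoint time series CSV
#'
#' Reads a wide per-frame keypoint table: one row per frame, columns named
#' `<landmark>_x`, `<landmark>_y`, `<landmark>_z`. Empty or unparseable
#' cells become missing values (occlusions).
#'
#' @param path path to the CSV file.
#' @param fps frames per second of the recording (positive).
#' @param required_landmarks landmarks that must be present; defaults to
#'   the core wrist/fingertip/torso set.
#' @param speaker_id,recording_id labels attached to the series.
#' @return A [skeleton_ts].
#' @export
read_keypoint_timeseries <- function(path, fps,
                                     required_landmarks = CORE_LANDMARKS,
                                     speaker_id = NA_character_,
                                     recording_id = NA_character_) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a positive scalar")
  if (!file.exists(path)) stop(sprintf("keypoint file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  present <- unique(sub("_(x|y|z)$", "", grep("_(x|y|z)$", names(df), value = TRUE)))
  absent <- setdiff(required_landmarks, present)
  if (length(absent))
    stop(sprintf("keypoint file %s is missing required landmark(s): %s",
                 path, paste(absent, collapse = ", ")))
  # coerce every coordinate column through as.numeric so stray text -> NA
  for (cl in grep("_(x|y|z)$", names(df), value = TRUE))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  skeleton_ts(df, fps = fps, landmarks = present,
              speaker_id = speaker_id, recording_id = recording_id)
}

#' Write a keypoint time series CSV
#'
#' Inverse of [read_keypoint_timeseries()]; missing values are written as
#' empty cells. Values are written with full double precision so a
#' write/read round-trip reproduces coordinates to better than 1e-9.
#'
#' @param series a [skeleton_ts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_keypoint_timeseries <- function(series, path) {
  stopifnot(inherits(series, "skeleton_ts"))
  lms <- landmark_names(series)
  cols <- list()
  for (lm in lms)
    for (ax in AXES)
      cols[[paste0(lm, "_", ax)]] <- series$coords[, lm, ax]
  df <- as.data.frame(cols, check.names = FALSE)
  .write_csv_precise(df, path)
  invisible(path)
}

# write.csv at full precision (17 significant digits), NA as empty cell
.write_csv_precise <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cl in names(df)[num]) {
    v <- format(df[[cl]], digits = 17, trim = TRUE, scientific = FALSE)
    v[is.na(df[[cl]])] <- ""
    out[[cl]] <- v
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
}

#' Read a gesture segment table
#'
#' Reads a tab-separated stroke table (the canonical ELAN export) with
#' columns `dyad`, `speaker`, `trial`, `t_start`, `t_end`, `handedness`.
#' Times are seconds.
#'
#' @param path path to the TSV file.
#' @return A list of [gesture_segment] objects, in file order.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("segment file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dyad", "speaker", "trial", "t_start", "t_end", "handedness")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("segment table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    seg <- tryCatch(
      gesture_segment(df$dyad[i], df$speaker[i], df$trial[i],
                      df$t_start[i], df$t_end[i], df$handedness[i]),
      error = function(e)
        stop(sprintf("segment table row %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    out[[i]] <- seg
  }
  out
}

#' Write a gesture segment table
#'
#' @param segments list of [gesture_segment] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  df <- data.frame(
    dyad = vapply(segments, `[[`, "", "dyad_id"),
    speaker = vapply(segments, `[[`, "", "speaker_id"),
    trial = vapply(segments, `[[`, "", "trial_id"),
    t_start = vapply(segments, `[[`, 0, "t_start"),
    t_end = vapply(segments, `[[`, 0, "t_end"),
    handedness = vapply(segments, `[[`, "", "handedness"))
  .write_csv_precise(df, path, sep = "\t")
  invisible(path)
}

#' Read a similarity annotation table
#'
#' Annotation CSVs carry one row per gesture pair: `pair_id`, the four
#' feature columns `handshape`, `movement`, `orientation`, `position`, and
#' optionally `handedness_match`. Ratings are binary or ordinal 0-5.
#'
#' @param path path to the CSV file.
#' @param scale `"binary"` or `"ordinal6"`.
#' @return A data frame with one validated row per pair.
#' @export
read_annotation_table <- function(path, scale = c("binary", "ordinal6")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "handshape", "movement", "orientation", "position")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("annotation table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  rng <- if (scale == "binary") c(0, 1) else 0:5
  for (f in FEATURES)
    if (!all(df[[f]] %in% rng))
      stop(sprintf("annotation column '%s' out of range for scale '%s'",
                   f, scale))
  attr(df, "scale") <- scale
  df
}

FEATURES <- c("handshape", "movement", "orientation", "position")

DISTANCE_TABLE_META <- c("pair_id", "dyad_id", "trial_id",
                         "pair_distance", "mirror_used",
                         "n_frames_a", "n_frames_b")

#' Write / read a distance table
#'
#' Distance tables hold one row per compared gesture pair: identifiers,
#' the pair-level normalized DTW distance, per-hand and per-keypoint
#' component distances, the mirror flag, and the two clip lengths. Column
#' order is stable and the round-trip is lossless to 1e-9.
#'
#' @param table a distance-table data frame as produced by
#'   [compute_pair_distances()].
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_distance_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(DISTANCE_TABLE_META, names(table))
  if (length(miss))
    stop(sprintf("distance table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(table), DISTANCE_TABLE_META)
  table <- table[, c(DISTANCE_TABLE_META, sort(extra)), drop = FALSE]
  .write_csv_precise(table, path)
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("distance file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("mirror_used" %in% names(df))
    df$mirror_used <- as.logical(df$mirror_used)
  df
}
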