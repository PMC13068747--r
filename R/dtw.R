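# Open-begin-end asymmetric DTW, the distance at the heart of the package.
#
# The asymmetric step pattern advances the query index by exactly one
# frame per step while the reference index advances by 0, 1, or 2, so
# every query frame is matched exactly once. Open begin/end lets the
# alignment enter and leave the reference anywhere at no cost, which makes
# the distance robust to imprecise stroke segmentation. The cumulative
# cost (one Euclidean local cost per step) is normalized by the total
# frame count of the two clips, so longer gestures do not accumulate
# larger distances merely by being longer.

#' Euclidean local cost between two frames
#'
#' @param a,b numeric coordinate vectors of equal length.
#' @return Nonnegative Euclidean distance.
#' @export
local_cost <- function(a, b) sqrt(sum((a - b)^2))

#' Open-begin-end asymmetric DTW between two trajectories
#'
#' Dynamic program over an `n x m` grid of local Euclidean costs. Steps
#' are `(+1, 0)`, `(+1, +1)`, `(+1, +2)` in (query, reference) indices;
#' the path may start at any reference column at zero entry cost and end
#' at any reference column (minimum over the final query row). Ties are
#' broken deterministically: smallest ending column first, and during
#' backtracking diagonal is preferred over repeating a reference frame,
#' which is preferred over skipping one.
#'
#' @param query numeric matrix `n x d` (each query frame matched once).
#' @param reference numeric matrix `m x d`.
#' @return A list of class `dtw_alignment`: `cumulative_cost`, `path`
#'   (two-column matrix of 1-based (query, reference) index pairs),
#'   `n`, `m`, `j_start`, `j_end`.
#' @export
dtw_open_begin_end <- function(query, reference) {
  query <- as.matrix(query); reference <- as.matrix(reference)
  n <- nrow(query); m <- nrow(reference)
  if (n < 2L || m < 2L)
    stop("both series need at least 2 frames (pad short clips first)")
  if (ncol(query) != ncol(reference))
    stop("query and reference must share the same coordinate dimension")
  cm <- .cost_matrix(query, reference)
  D <- matrix(NA_real_, n, m)
  ch <- matrix(0L, n, m)       # 1 = repeat (+0), 2 = diagonal (+1), 3 = skip (+2)
  D[1, ] <- cm[1, ]            # open begin: free entry at any column
  for (i in 2:n) {
    prev <- D[i - 1L, ]
    diag_ <- c(Inf, prev[-m])
    skip <- if (m > 2L) c(Inf, Inf, prev[1:(m - 2L)]) else rep(Inf, m)
    # tie preference: diagonal > repeat > skip (strict improvement to switch)
    best <- diag_; step <- rep(2L, m)
    imp <- prev < best; best[imp] <- prev[imp]; step[imp] <- 1L
    imp <- skip < best; best[imp] <- skip[imp]; step[imp] <- 3L
    D[i, ] <- cm[i, ] + best
    ch[i, ] <- step
  }
  j_end <- which.min(D[n, ])   # ties: smallest column
  # backtrack
  path <- matrix(NA_integer_, n, 2L)
  j <- j_end
  for (i in n:1) {
    path[i, ] <- c(i, j)
    if (i > 1L) j <- j - (ch[i, j] - 1L)
  }
  structure(list(cumulative_cost = D[n, j_end], path = path,
                 n = n, m = m, j_start = path[1, 2], j_end = j_end),
            class = "dtw_alignment")
}

# coordinate-wise differences rather than the Gram-matrix identity:
# exact zeros for identical frames, which open-end subsequence matches rely on
.cost_matrix <- function(q, r) {
  n <- nrow(q); m <- nrow(r)
  d2 <- matrix(0, n, m)
  for (k in seq_len(ncol(q)))
    d2 <- d2 + (matrix(q[, k], n, m) - matrix(r[, k], n, m, byrow = TRUE))^2
  sqrt(d2)
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment> cost %.6g, query n=%d vs reference m=%d, ref window [%d, %d]\n",
              x$cumulative_cost, x$n, x$m, x$j_start, x$j_end))
  invisible(x)
}

#' Frame-count normalization of a cumulative DTW cost
#'
#' Cumulative alignment cost grows with gesture length; dividing by the
#' total number of frames of the two clips (`n + m`) yields a
#' length-comparable distance.
#'
#' @param cumulative_cost nonnegative alignment cost.
#' @param n,m frame counts of the two clips.
#' @return `cumulative_cost / (n + m)`.
#' @export
normalized_distance <- function(cumulative_cost, n, m) {
  stopifnot(cumulative_cost >= 0, n >= 1, m >= 1)
  cumulative_cost / (n + m)
}

#' Normalized DTW distance between one hand of each clip
#'
#' Runs open-begin-end DTW separately on each of the six hand keypoints
#' (wrist + five fingertips) of `hand_a` in `clip_a` against `hand_b` in
#' `clip_b`, normalizes each cumulative cost by the total frame count, and
#' averages across the six keypoints.
#'
#' @param clip_a,clip_b preprocessed `gesture_clip`s (wrist-relative
#'   fingertips applied). `clip_a` is the query.
#' @param hand_a,hand_b `"left"` or `"right"`.
#' @param use_z include the z coordinate in the local cost.
#' @param symmetrize average the query/reference roles both ways.
#' @return List with `per_keypoint` (named length-6 vector) and
#'   `per_hand` (their mean).
#' @export
hand_distance <- function(clip_a, clip_b, hand_a, hand_b,
                          use_z = FALSE, symmetrize = FALSE) {
  stopifnot(inherits(clip_a, "gesture_clip"), inherits(clip_b, "gesture_clip"))
  hand_a <- match.arg(hand_a, c("left", "right"))
  hand_b <- match.arg(hand_b, c("left", "right"))
  axes <- if (use_z) c("x", "y", "z") else c("x", "y")
  n <- clip_a$n_frames; m <- clip_b$n_frames
  per_kp <- vapply(HAND_KEYPOINTS, function(kp) {
    ta <- trajectory(clip_a$series, paste0(hand_a, "_", kp), axes)
    tb <- trajectory(clip_b$series, paste0(hand_b, "_", kp), axes)
    d <- normalized_distance(dtw_open_begin_end(ta, tb)$cumulative_cost, n, m)
    if (symmetrize) {
      d2 <- normalized_distance(dtw_open_begin_end(tb, ta)$cumulative_cost, m, n)
      d <- (d + d2) / 2
    }
    d
  }, numeric(1))
  list(per_keypoint = per_kp, per_hand = mean(per_kp))
}

#' Mirror-flip a skeleton time series
#'
#' Negates x for every landmark and swaps left/right landmark labels, the
#' geometric mirror about the body midline of a position-normalized
#' series. Applying it twice restores the input.
#'
#' @param series a position-normalized [skeleton_ts] (mid-torso at the
#'   origin, so the midline is x = 0).
#' @return The mirrored [skeleton_ts].
#' @export
mirror_flip <- function(series) {
  stopifnot(inherits(series, "skeleton_ts"))
  out <- series
  out$coords[, , "x"] <- -series$coords[, , "x"]
  lms <- landmark_names(series)
  swapped <- ifelse(startsWith(lms, "left_"),
                    sub("^left_", "right_", lms),
                    ifelse(startsWith(lms, "right_"),
                           sub("^right_", "left_", lms), lms))
  # relabel: coords of the original left landmarks now describe the right
  dimnames(out$coords)[[2]] <- swapped
  out$coords <- out$coords[, lms, , drop = FALSE]   # restore column order
  out
}

.mirror_clip <- function(clip) {
  clip$series <- mirror_flip(clip$series)
  h <- clip$segment$handedness
  clip$segment$handedness <- switch(h, left = "right", right = "left", h)
  clip
}

#' Mirror-rule selection between two candidate distances
#'
#' For one-handed gestures produced with opposite hands, the pipeline
#' computes the distance for the original orientation and for the second
#' speaker's mirror-flipped gesture, and adopts the lower one (for
#' example, original 0.5 vs flipped 0.1 adopts 0.1). Ties keep the
#' original.
#'
#' @param original,flipped nonnegative candidate distances.
#' @return List with `distance` (the adopted value) and `mirror_used`.
#' @export
mirror_select <- function(original, flipped) {
  stopifnot(original >= 0, flipped >= 0)
  if (flipped < original) list(distance = flipped, mirror_used = TRUE)
  else list(distance = original, mirror_used = FALSE)
}

#' Mirror-adjusted distance for opposite-handed one-handed pairs
#'
#' Computes the cross-hand distance between the two original clips and
#' the same-side distance after mirror-flipping the second clip, then
#' adopts the minimum via [mirror_select()].
#'
#' @param clip_a,clip_b preprocessed one-handed `gesture_clip`s with
#'   opposite handedness.
#' @inheritParams hand_distance
#' @return A `distance_result` (see [pair_distance()]).
#' @export
mirrored_pair_distance <- function(clip_a, clip_b,
                                   use_z = FALSE, symmetrize = FALSE) {
  ha <- clip_a$segment$handedness; hb <- clip_b$segment$handedness
  if (!(ha %in% c("left", "right") && hb %in% c("left", "right") && ha != hb))
    stop("mirror rule applies only to one-handed pairs with opposite hands")
  orig <- hand_distance(clip_a, clip_b, ha, hb, use_z, symmetrize)
  flip <- hand_distance(clip_a, .mirror_clip(clip_b), ha, ha, use_z, symmetrize)
  sel <- mirror_select(orig$per_hand, flip$per_hand)
  win <- if (sel$mirror_used) flip else orig
  .distance_result(comparisons = list(cross = win),
                   pair_distance = sel$distance,
                   mirror_used = sel$mirror_used,
                   branch = if (sel$mirror_used) "opposite_hands_mirrored"
                            else "opposite_hands_original",
                   clip_a = clip_a, clip_b = clip_b)
}

.distance_result <- function(comparisons, pair_distance, mirror_used,
                             branch, clip_a, clip_b) {
  per_hand <- vapply(comparisons, `[[`, numeric(1), "per_hand")
  kp <- sapply(comparisons, `[[`, "per_keypoint")   # 6 x k matrix or vector
  kp <- if (is.matrix(kp)) rowMeans(kp) else kp
  structure(list(per_keypoint = kp, per_hand = per_hand,
                 pair_distance = pair_distance, mirror_used = mirror_used,
                 branch = branch,
                 n_frames_a = clip_a$n_frames, n_frames_b = clip_b$n_frames),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> %.6g (%s%s)\n", x$pair_distance, x$branch,
              if (x$mirror_used) ", mirrored" else ""))
  invisible(x)
}

#' Pair-level normalized DTW distance with gesturing-hand selection
#'
#' Aggregates hand-level distances over the gesturing hands only:
#' two-handed vs two-handed averages the left-left and right-right
#' comparisons; one-handed pairs on the same side compare that side only;
#' one-handed pairs on opposite sides are compared cross-hand, with the
#' mirror-flip minimum rule applied when `mirror = TRUE`; a one-handed vs
#' two-handed pair takes the minimum over the single hand compared with
#' each of the other speaker's hands.
#'
#' @param clip_a,clip_b preprocessed `gesture_clip`s carrying handedness
#'   labels; `clip_a` is the query.
#' @param use_z include z in the local cost.
#' @param mirror apply the mirror-flip minimum rule to opposite-handed
#'   one-handed pairs.
#' @param symmetrize average both query/reference directions.
#' @return A `distance_result`: `per_keypoint` (length-6, averaged over
#'   the comparisons used), `per_hand` (one value per comparison),
#'   `pair_distance`, `mirror_used`, `branch`, `n_frames_a`, `n_frames_b`.
#' @export
pair_distance <- function(clip_a, clip_b, use_z = FALSE,
                          mirror = TRUE, symmetrize = FALSE) {
  ha <- clip_a$segment$handedness; hb <- clip_b$segment$handedness
  if (is.null(ha) || is.null(hb) || is.na(ha) || is.na(hb))
    stop("both clips must carry a handedness label")
  hd <- function(h1, h2, cb = clip_b)
    hand_distance(clip_a, cb, h1, h2, use_z, symmetrize)
  if (ha == "both" && hb == "both") {
    cmp <- list(left = hd("left", "left"), right = hd("right", "right"))
    return(.distance_result(cmp, mean(vapply(cmp, `[[`, 0, "per_hand")),
                            FALSE, "both_hands", clip_a, clip_b))
  }
  if (ha %in% c("left", "right") && hb %in% c("left", "right")) {
    if (ha == hb) {
      cmp <- list(hd(ha, hb)); names(cmp) <- ha
      return(.distance_result(cmp, cmp[[1]]$per_hand, FALSE,
                              paste0("same_hand_", ha), clip_a, clip_b))
    }
    if (mirror) return(mirrored_pair_distance(clip_a, clip_b, use_z, symmetrize))
    cmp <- list(cross = hd(ha, hb))
    return(.distance_result(cmp, cmp$cross$per_hand, FALSE,
                            "opposite_hands_original", clip_a, clip_b))
  }
  # one-handed vs two-handed: compare the single hand with each of the
  # other speaker's hands and keep the lower
  single_first <- ha %in% c("left", "right")
  sh <- if (single_first) ha else hb
  cand <- lapply(c("left", "right"), function(other)
    if (single_first) hd(sh, other) else hd(other, sh))
  names(cand) <- c("left", "right")
  pick <- which.min(vapply(cand, `[[`, 0, "per_hand"))
  cmp <- cand[pick]
  .distance_result(cmp, cmp[[1]]$per_hand, FALSE,
                   sprintf("single_vs_both_%s", names(cand)[pick]),
                   clip_a, clip_b)
}

#' Compute distances for a table of gesture pairs
#'
#' Vectorized driver: takes a named list of preprocessed clips and a pair
#' table with columns `pair_id`, `clip_a`, `clip_b` (names into the clip
#' list) plus optional `dyad_id` / `trial_id`, and returns a flat distance
#' table with one row per pair.
#'
#' @param clips named list of preprocessed `gesture_clip`s.
#' @param pairs data frame describing the pairs to compare.
#' @param use_z,mirror,symmetrize passed to [pair_distance()].
#' @return A data frame with identifier columns, `pair_distance`,
#'   `mirror_used`, `branch`, clip lengths and per-keypoint means
#'   (`kp_wrist`, ..., `kp_pinky_tip`).
#' @export
compute_pair_distances <- function(clips, pairs, use_z = FALSE,
                                   mirror = TRUE, symmetrize = FALSE) {
  stopifnot(all(c("pair_id", "clip_a", "clip_b") %in% names(pairs)))
  miss <- setdiff(unique(c(pairs$clip_a, pairs$clip_b)), names(clips))
  if (length(miss))
    stop(sprintf("pair table references unknown clip(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- pair_distance(clips[[pairs$clip_a[i]]], clips[[pairs$clip_b[i]]],
                         use_z = use_z, mirror = mirror,
                         symmetrize = symmetrize)
    kp <- as.list(res$per_keypoint)
    names(kp) <- paste0("kp_", HAND_KEYPOINTS)
    c(list(pair_id = pairs$pair_id[i],
           dyad_id = if ("dyad_id" %in% names(pairs)) pairs$dyad_id[i] else NA,
           trial_id = if ("trial_id" %in% names(pairs)) pairs$trial_id[i] else NA,
           pair_distance = res$pair_distance,
           mirror_used = res$mirror_used,
           branch = res$branch,
           n_frames_a = res$n_frames_a, n_frames_b = res$n_frames_b),
      kp)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
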