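# Validation statistics: the computations that relate the continuous DTW
# distance to human feature-level similarity coding. Overall similarity
# for a pair is the overlap count -- how many of the four form features
# (handshape, movement, orientation, position) were rated similar;
# handedness is excluded because the distance already conditions on
# gesturing hands. If the distance captures form similarity, it should
# correlate negatively with the overlap count.

#' Binarize an ordinal similarity rating
#'
#' Ordinal 0-5 ratings are recoded so scores of 4 and 5 count as similar
#' and 0-3 as not similar, which keeps the share of "similar" ratings
#' comparable with binary-coded corpora.
#'
#' @param score numeric vector of ratings in 0..5.
#' @return Integer vector of 0/1.
#' @export
binarize_rating <- function(score) {
  if (!all(score %in% 0:5)) stop("ordinal ratings must lie in 0..5")
  as.integer(score >= 4)
}

#' Number of overlapping form features
#'
#' Sums the binary similarity ratings for handshape, movement,
#' orientation and position (0-4). Ordinal annotations are binarized
#' first. Handedness never enters the count.
#'
#' @param annotation a [similarity_annotation], or a data frame with the
#'   four feature columns (one row per pair).
#' @return Integer overlap count(s) in 0..4.
#' @export
overlap_count <- function(annotation) {
  if (inherits(annotation, "similarity_annotation")) {
    r <- annotation$ratings
    if (annotation$scale == "ordinal6") r <- binarize_rating(r)
    return(as.integer(sum(r)))
  }
  stopifnot(is.data.frame(annotation), all(FEATURES %in% names(annotation)))
  m <- as.matrix(annotation[, FEATURES])
  if (any(!m %in% c(0, 1))) m <- apply(m, 2, binarize_rating)
  as.integer(rowSums(m))
}

#' Spearman rank correlation with permutation or t-approximation p-value
#'
#' The coefficient is the Pearson correlation of average ranks (base R's
#' tie handling). The two-sided p-value comes from exhaustive permutation
#' enumeration for n <= 8, Monte Carlo permutation for n <= 20, and the
#' t approximation beyond that; `method` forces a specific route.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"auto"`, `"t_approximation"` or `"permutation"`.
#' @param n_perm Monte Carlo draws when enumeration is infeasible.
#' @return A list of class `correlation_result`: `rho`, `n`, `p_value`,
#'   `method`.
#' @export
spearman_cor <- function(x, y, method = c("auto", "t_approximation",
                                          "permutation"),
                         n_perm = 9999) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "auto")
    method <- if (n > 20) "t_approximation" else "permutation"
  p <- if (method == "t_approximation") {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    .perm_p(rx, ry, rho, n_perm)
  }
  structure(list(rho = rho, n = n, p_value = min(p, 1), method = method),
            class = "correlation_result")
}

# two-sided permutation p-value for |rho|; exhaustive when n! is small.
# Pearson r of ranks computed in closed form over a permutation matrix so
# enumeration stays fast enough for repeated calibration runs.
.perm_p <- function(rx, ry, rho, n_perm) {
  n <- length(rx)
  sd_pop <- function(v) sqrt(mean(v^2) - mean(v)^2)
  denom <- sd_pop(rx) * sd_pop(ry)
  if (n <= 8) {
    perms <- .perm_cache(n)
    s <- as.numeric(matrix(ry[perms], nrow(perms), n) %*% rx)
    rhos <- (s / n - mean(rx) * mean(ry)) / denom
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    draws <- vapply(seq_len(n_perm), function(i) sum(rx * sample(ry)),
                    numeric(1))
    rhos <- (draws / n - mean(rx) * mean(ry)) / denom
    (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
}

.perm_env <- new.env(parent = emptyenv())
.perm_cache <- function(n) {
  key <- as.character(n)
  if (is.null(.perm_env[[key]])) .perm_env[[key]] <- .all_permutations(n)
  .perm_env[[key]]
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d), p = %.4g [%s]\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' Dyad- and item-adjusted slope of distance on overlap
#'
#' A fixed-effects approximation to a mixed model with by-dyad and
#' by-item varying intercepts: both variables are two-way within
#' transformed (dyad means and item means subtracted, grand mean added
#' back) and the slope comes from ordinary least squares on the demeaned
#' data, with heteroskedasticity-robust (HC1) standard errors.
#'
#' @param distance,overlap numeric vectors.
#' @param dyad_ids,item_ids grouping labels, same length.
#' @return A list of class `demeaned_slope`: `slope`, `se`, `t`,
#'   `p_value`, `n`, and `note` labelling the approximation.
#' @export
demeaned_slope <- function(distance, overlap, dyad_ids, item_ids) {
  n <- length(distance)
  stopifnot(length(overlap) == n, length(dyad_ids) == n,
            length(item_ids) == n)
  if (stats::sd(overlap) == 0)
    stop("slope undefined: overlap is constant")
  dm <- function(v) {
    v - stats::ave(v, dyad_ids) - stats::ave(v, item_ids) + mean(v)
  }
  d <- dm(distance); o <- dm(overlap)
  if (stats::sd(o) == 0)
    stop("slope undefined: overlap is constant within the grouping structure")
  fit <- stats::lm(d ~ o)
  vc <- sandwich::vcovHC(fit, type = "HC1")
  slope <- stats::coef(fit)[["o"]]
  se <- sqrt(vc["o", "o"])
  tt <- slope / se
  structure(list(slope = slope, se = se, t = tt,
                 p_value = 2 * stats::pt(-abs(tt), df = fit$df.residual),
                 n = n,
                 note = "two-way within OLS approximation to a dyad/item random-intercept model"),
            class = "demeaned_slope")
}

#' @export
print.demeaned_slope <- function(x, ...) {
  cat(sprintf("demeaned slope = %.4f (SE %.4f, t = %.2f, p = %.4g, n = %d)\n  [%s]\n",
              x$slope, x$se, x$t, x$p_value, x$n, x$note))
  invisible(x)
}

#' Validate a distance table against similarity annotations
#'
#' Joins the distance table with the annotation table on `pair_id` and
#' reports: the Spearman correlation between the pair distance and the
#' overlap count, per-feature distance summaries (mean distance for
#' pairs rated similar vs not), the dyad/item-demeaned slope, and
#' incongruent pairs (top distance quartile with overlap >= 3, or bottom
#' quartile with overlap <= 1) worth a qualitative look.
#'
#' @param distance_table data frame from [compute_pair_distances()] or
#'   [read_distance_table()].
#' @param annotations data frame with `pair_id` plus the four feature
#'   columns (binary or ordinal).
#' @return A list of class `validation_report`.
#' @export
validate_corpus <- function(distance_table, annotations) {
  stopifnot(is.data.frame(distance_table), is.data.frame(annotations))
  if (nrow(annotations) == 0) stop("annotation set is empty")
  df <- merge(distance_table, annotations, by = "pair_id")
  if (nrow(df) == 0) stop("no pair_id overlap between distances and annotations")
  df$overlap <- overlap_count(df[, FEATURES])
  rho <- spearman_cor(df$pair_distance, df$overlap)
  feat <- lapply(FEATURES, function(f) {
    b <- if (all(df[[f]] %in% c(0, 1))) df[[f]] else binarize_rating(df[[f]])
    c(mean_dist_similar = mean(df$pair_distance[b == 1]),
      mean_dist_not_similar = mean(df$pair_distance[b == 0]),
      n_similar = sum(b == 1), n_not_similar = sum(b == 0))
  })
  names(feat) <- FEATURES
  slope <- tryCatch(
    demeaned_slope(df$pair_distance, df$overlap, df$dyad_id, df$trial_id),
    error = function(e) NULL)
  q <- stats::quantile(df$pair_distance, c(0.25, 0.75))
  incong <- df[(df$pair_distance >= q[2] & df$overlap >= 3) |
               (df$pair_distance <= q[1] & df$overlap <= 1),
               c("pair_id", "pair_distance", "overlap")]
  structure(list(n_pairs = nrow(df), spearman = rho,
                 per_feature = feat, demeaned = slope,
                 incongruent = incong),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d pairs\n", x$n_pairs))
  cat("  "); print(x$spearman)
  if (!is.null(x$demeaned)) { cat("  "); print(x$demeaned) }
  for (f in names(x$per_feature)) {
    v <- x$per_feature[[f]]
    cat(sprintf("  %-12s mean distance %.3f (similar, n=%d) vs %.3f (not, n=%d)\n",
                f, v["mean_dist_similar"], v["n_similar"],
                v["mean_dist_not_similar"], v["n_not_similar"]))
  }
  cat(sprintf("  %d incongruent pair(s) flagged for qualitative review\n",
              nrow(x$incongruent)))
  invisible(x)
}
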