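# Independent oracles and fixture builders used across the suite.

# Exhaustive enumeration of every admissible asymmetric open-begin-end
# path (reference increments in {0,1,2} per query step, free entry and
# exit). Independent of the package's dynamic program.
bf_dtw_cost <- function(q, r) {
  n <- nrow(q); m <- nrow(r)
  cm <- as.matrix(dist(rbind(q, r)))[1:n, (n + 1):(n + m), drop = FALSE]
  incs <- as.matrix(expand.grid(rep(list(0:2), n - 1)))
  cs <- incs
  if (ncol(cs) > 1)
    for (cc in 2:ncol(cs)) cs[, cc] <- cs[, cc - 1] + cs[, cc]
  best <- Inf
  for (j0 in 1:m) {
    jm <- cbind(j0, j0 + cs)
    ok <- jm[, n] <= m
    if (!any(ok)) next
    jm <- jm[ok, , drop = FALSE]
    cost <- numeric(nrow(jm))
    for (i in 1:n) cost <- cost + cm[cbind(i, jm[, i])]
    best <- min(best, min(cost))
  }
  best
}

# Second independent route for larger instances: the alignment lattice as
# a DAG (edge into node (i,j) weighted by the local cost at (i,j), free
# source into row 1, minimum over row n) solved by igraph's shortest-path
# machinery.
ig_dtw_cost <- function(q, r) {
  n <- nrow(q); m <- nrow(r)
  cm <- as.matrix(dist(rbind(q, r)))[1:n, (n + 1):(n + m), drop = FALSE]
  id <- function(i, j) (i - 1L) * m + j
  S <- n * m + 1L
  from <- rep(S, m); to <- id(1, 1:m); w <- cm[1, ]
  for (i in 2:n) for (dj in 0:2) {
    js <- (1 + dj):m
    if (js[1] > m) next
    from <- c(from, id(i - 1, js - dj))
    to <- c(to, id(i, js))
    w <- c(w, cm[i, js])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to))
  min(igraph::distances(g, v = S, to = id(n, 1:m), mode = "out", weights = w))
}

# smooth 2-D random-walk trajectory, the shape DTW sees after smoothing
random_walk_traj <- function(n, sd = 0.05) {
  apply(matrix(stats::rnorm(n * 2, sd = sd), n), 2, cumsum)
}

# random fully-observed skeleton series for round-trip and invariance tests
random_skeleton <- function(n = 12, fps = 30, na_frac = 0) {
  arr <- array(stats::runif(n * length(CORE_LANDMARKS) * 3),
               c(n, length(CORE_LANDMARKS), 3),
               dimnames = list(NULL, CORE_LANDMARKS, c("x", "y", "z")))
  if (na_frac > 0) {
    drop <- sample(length(arr), floor(na_frac * length(arr)))
    arr[drop] <- NA
    # keep at least frame 1 observed everywhere so interpolation stays legal
    arr[1, , ] <- stats::runif(length(CORE_LANDMARKS) * 3)
  }
  skeleton_ts(arr, fps = fps)
}

# wrap a whole series as a gesture clip without stroke extraction
as_clip <- function(series, handedness = "right") {
  seg <- gesture_segment("d", "s", "t", 0, n_frames(series) / series$fps,
                         handedness)
  structure(list(segment = seg, series = series,
                 n_frames = n_frames(series), padded = FALSE,
                 pad_before = 0L, pad_after = 0L,
                 first_frame = 1L, last_frame = n_frames(series)),
            class = "gesture_clip")
}

# preprocessed clip pair from a pair_spec, via the real pipeline
preprocessed_pair <- function(ps, config = preprocess_config()) {
  rp <- render_pair(ps)
  mk <- function(g) {
    pre <- run_pipeline(g$series, config)
    extract_clip(pre, g$segment)
  }
  list(a = mk(rp$a), b = mk(rp$b), annotation = rp$annotation)
}

# permutations by Heap's algorithm -- deliberately different from the
# package's recursive-insertion enumerator
heap_permutations <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1L) { out[[length(out) + 1L]] <<- a; return(invisible()) }
    for (i in seq_len(k)) {
      rec(k - 1L)
      if (k %% 2L == 0L) { tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp }
      else { tmp <- a[1L]; a[1L] <<- a[k]; a[k] <<- tmp }
    }
  }
  rec(n)
  do.call(rbind, out)
}

# shared 200-pair corpus, generated once per test run
.corpus_cache <- new.env(parent = emptyenv())
std_corpus <- function() {
  if (is.null(.corpus_cache$c200))
    .corpus_cache$c200 <- generate_corpus(n_pairs = 200, n_dyads = 10,
                                          n_items = 16, seed = 42)
  .corpus_cache$c200
}
std_distances <- function() {
  if (is.null(.corpus_cache$d200)) {
    corpus <- std_corpus()
    .corpus_cache$d200 <- run_all(run_config(seed = 42), corpus = corpus)
  }
  .corpus_cache$d200
}
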