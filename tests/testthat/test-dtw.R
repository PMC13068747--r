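test_that("the local cost is the Euclidean metric on active coordinates", {
  expect_equal(local_cost(c(1, 2), c(1, 2)), 0)
  expect_equal(local_cost(c(0, 0), c(3, 4)), 5)
  expect_equal(local_cost(c(1, 7), c(-2, 5)), local_cost(c(-2, 5), c(1, 7)))
})

test_that("aligning a series with itself costs zero along the diagonal", {
  set.seed(41)
  q <- random_walk_traj(12)
  al <- dtw_open_begin_end(q, q)
  expect_equal(al$cumulative_cost, 0)
  expect_equal(al$path[, 1], al$path[, 2])
  expect_equal(al$j_start, 1L)
  expect_equal(al$j_end, 12L)
})

test_that("an exactly embedded query ignores non-matching flanks for free", {
  set.seed(42)
  core <- random_walk_traj(8)
  flank1 <- matrix(5 + runif(6 * 2), 6)
  flank2 <- matrix(-5 - runif(4 * 2), 4)
  ref <- rbind(flank1, core, flank2)
  al <- dtw_open_begin_end(core, ref)
  expect_equal(al$cumulative_cost, 0, tolerance = 1e-12)
  expect_equal(al$j_start, 7L)
  expect_equal(al$j_end, 14L)
})

test_that("DP cost equals exhaustive path enumeration on small instances", {
  set.seed(43)
  for (k in 1:250) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    q <- matrix(rnorm(n * 2), n); r <- matrix(rnorm(m * 2), m)
    expect_equal(dtw_open_begin_end(q, r)$cumulative_cost,
                 bf_dtw_cost(q, r), tolerance = 1e-10)
  }
})

test_that("alignment paths obey the asymmetric step constraints", {
  set.seed(44)
  for (k in 1:50) {
    n <- sample(3:25, 1); m <- sample(3:25, 1)
    al <- dtw_open_begin_end(random_walk_traj(n), random_walk_traj(m))
    expect_equal(al$path[, 1], seq_len(n))           # query advances by 1
    dj <- diff(al$path[, 2])
    expect_true(all(dj %in% 0:2))                    # reference by 0, 1 or 2
    expect_true(al$j_start >= 1 && al$j_start <= al$j_end && al$j_end <= m)
    expect_gte(al$cumulative_cost, 0)
  }
})

test_that("degenerate inputs are rejected", {
  q <- random_walk_traj(5)
  expect_error(dtw_open_begin_end(q[1, , drop = FALSE], q), "2 frames")
  expect_error(dtw_open_begin_end(q, q[, 1, drop = FALSE]), "dimension")
})

test_that("normalization divides the cumulative cost by the total frames", {
  expect_equal(normalized_distance(2.0, 6, 4), 0.2)
  expect_equal(normalized_distance(0, 5, 99), 0)
  # duplicating every frame of smooth inputs leaves the normalized value
  # within a small factor of the original
  set.seed(45)
  q <- random_walk_traj(20, sd = 0.02); r <- random_walk_traj(24, sd = 0.02)
  d1 <- normalized_distance(dtw_open_begin_end(q, r)$cumulative_cost, 20, 24)
  q2 <- q[rep(1:20, each = 2), ]; r2 <- r[rep(1:24, each = 2), ]
  d2 <- normalized_distance(dtw_open_begin_end(q2, r2)$cumulative_cost, 40, 48)
  expect_lt(abs(d2 - d1), 0.5 * max(d1, 0.01))
})

test_that("hand distance is the mean of six per-keypoint distances", {
  ps <- pair_spec(gesture_spec(hand = "right"), noise_sd = 0.003,
                  occlusion_rate = 0)
  set.seed(46)
  pp <- preprocessed_pair(ps)
  hd <- hand_distance(pp$a, pp$b, "right", "right")
  expect_named(hd$per_keypoint, HAND_KEYPOINTS)
  expect_equal(hd$per_hand, mean(hd$per_keypoint))
  expect_true(all(hd$per_keypoint >= 0))
  # identical clips: zero
  self <- hand_distance(pp$a, pp$a, "right", "right")
  expect_equal(self$per_hand, 0)
  expect_error(hand_distance(pp$a, pp$b, "up", "right"))
})

test_that("hand distance grows monotonically with added coordinate noise", {
  ps <- pair_spec(gesture_spec(hand = "right"), noise_sd = 0,
                  occlusion_rate = 0)
  set.seed(47)
  pp <- preprocessed_pair(ps)
  levels <- seq(0, 0.8, length.out = 20)
  d <- vapply(levels, function(sd) {
    b <- pp$b
    set.seed(470)
    b$series$coords <- b$series$coords +
      array(rnorm(length(b$series$coords), 0, sd), dim(b$series$coords))
    hand_distance(pp$a, b, "right", "right")$per_hand
  }, numeric(1))
  expect_gte(suppressWarnings(cor(d, levels, method = "spearman")), 0.9)
})

test_that("pair distance selects gesturing hands by handedness branch", {
  set.seed(48)
  pp_r <- preprocessed_pair(pair_spec(gesture_spec(hand = "right"),
                                      noise_sd = 0.002, occlusion_rate = 0))
  res <- pair_distance(pp_r$a, pp_r$b)
  expect_identical(res$branch, "same_hand_right")
  expect_equal(res$pair_distance, unname(res$per_hand[1]))

  pp_b <- preprocessed_pair(pair_spec(gesture_spec(hand = "both"),
                                      noise_sd = 0.002, occlusion_rate = 0))
  res_b <- pair_distance(pp_b$a, pp_b$b)
  expect_identical(res_b$branch, "both_hands")
  expect_named(res_b$per_hand, c("left", "right"))
  expect_equal(res_b$pair_distance, mean(res_b$per_hand))
  expect_equal(res_b$per_hand[["left"]],
               hand_distance(pp_b$a, pp_b$b, "left", "left")$per_hand)

  # one-handed vs two-handed: minimum over the other speaker's hands
  res_m <- pair_distance(pp_r$a, pp_b$b)
  expect_match(res_m$branch, "single_vs_both")
  d_l <- hand_distance(pp_r$a, pp_b$b, "right", "left")$per_hand
  d_r <- hand_distance(pp_r$a, pp_b$b, "right", "right")$per_hand
  expect_equal(res_m$pair_distance, min(d_l, d_r))

  bad <- pp_r$a; bad$segment$handedness <- NA
  expect_error(pair_distance(bad, pp_r$b), "handedness")
})

test_that("identical clips give zero pair distance with the mean identity", {
  set.seed(49)
  pp <- preprocessed_pair(pair_spec(gesture_spec(hand = "both"),
                                    noise_sd = 0.003, occlusion_rate = 0))
  res <- pair_distance(pp$a, pp$a)
  expect_equal(res$pair_distance, 0)
  expect_equal(unname(res$pair_distance), mean(res$per_keypoint))
})

test_that("mirror flip negates x, swaps sides, and is an involution", {
  set.seed(50)
  s <- random_skeleton(n = 6)
  np <- normalize_position(s)$series
  fl <- mirror_flip(np)
  expect_equal(fl$coords[, "right_wrist", "x"], -np$coords[, "left_wrist", "x"])
  expect_equal(fl$coords[, "right_wrist", "y"], np$coords[, "left_wrist", "y"])
  expect_equal(mirror_flip(fl)$coords, np$coords)
  expect_identical(landmark_names(fl), landmark_names(np))
})

test_that("flipping a midline-symmetric gesture swaps hand distances exactly", {
  # construct a clip symmetric about the midline: a two-handed mirror gesture
  spec <- gesture_spec(hand = "both", amplitude = 0.16)
  g <- render_gesture(spec)
  pre <- run_pipeline(g$series)
  clip <- extract_clip(pre, g$segment)
  flip <- clip; flip$series <- mirror_flip(clip$series)
  d_ll <- hand_distance(clip, clip, "left", "left")$per_hand
  d_lf <- hand_distance(clip, flip, "left", "left")$per_hand
  expect_lt(abs(d_ll - d_lf), 1e-9)
})

test_that("the mirror rule adopts the smaller distance, original on ties", {
  expect_equal(mirror_select(0.5, 0.1),
               list(distance = 0.1, mirror_used = TRUE))
  expect_equal(mirror_select(0.1, 0.5),
               list(distance = 0.1, mirror_used = FALSE))
  expect_equal(mirror_select(0.3, 0.3),
               list(distance = 0.3, mirror_used = FALSE))
})

test_that("mirrored one-handed pairs are recovered by the flip comparison", {
  set.seed(51)
  pp <- preprocessed_pair(pair_spec(gesture_spec(hand = "left"),
                                    mirror = TRUE, noise_sd = 0,
                                    occlusion_rate = 0))
  expect_identical(pp$a$segment$handedness, "left")
  expect_identical(pp$b$segment$handedness, "right")
  res <- mirrored_pair_distance(pp$a, pp$b)
  expect_true(res$mirror_used)
  expect_lt(res$pair_distance, 1e-6)     # exact mirror, noiseless
  # plain cross-hand distance is much larger
  plain <- pair_distance(pp$a, pp$b, mirror = FALSE)
  expect_gt(plain$pair_distance, res$pair_distance)
  expect_error(mirrored_pair_distance(pp$a, pp$a), "opposite")
})

test_that("the mirror rule never increases the distance", {
  set.seed(52)
  for (k in 1:8) {
    ps <- pair_spec(gesture_spec(hand = sample(c("left", "right"), 1)),
                    perturb = sample(c("handshape", "movement",
                                       "orientation", "position"),
                                     sample(0:2, 1)),
                    mirror = runif(1) < 0.5,
                    noise_sd = 0.004, occlusion_rate = 0)
    pp <- preprocessed_pair(ps)
    if (pp$a$segment$handedness == pp$b$segment$handedness) next
    with_rule <- pair_distance(pp$a, pp$b, mirror = TRUE)
    without <- pair_distance(pp$a, pp$b, mirror = FALSE)
    expect_lte(with_rule$pair_distance, without$pair_distance + 1e-12)
  }
})
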