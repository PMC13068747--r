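# helper: minimal series where one landmark's x carries a chosen vector
series_with_x <- function(v) {
  arr <- array(0.5, c(length(v), length(CORE_LANDMARKS), 3),
               dimnames = list(NULL, CORE_LANDMARKS, c("x", "y", "z")))
  arr[, "right_wrist", "x"] <- v
  skeleton_ts(arr, fps = 30)
}

test_that("linear interpolation fills interior gaps and copies at edges", {
  s <- interpolate_missing(series_with_x(c(1, 2, NA, NA, 5)))
  expect_equal(s$coords[, "right_wrist", "x"], c(1, 2, 3, 4, 5))
  s2 <- interpolate_missing(series_with_x(c(NA, 4, NA)))
  expect_equal(s2$coords[, "right_wrist", "x"], c(4, 4, 4))
  full <- series_with_x(c(1, 5, 2))
  expect_equal(interpolate_missing(full)$coords, full$coords)
  # idempotent
  expect_equal(interpolate_missing(s)$coords, s$coords)
})

test_that("a fully missing landmark track is reported by name", {
  s <- series_with_x(c(1, 2, 3))
  s$coords[, "left_thumb_tip", "y"] <- NA
  expect_error(interpolate_missing(s), "left_thumb_tip")
})

test_that("Gaussian smoothing reproduces its kernel and respects sigma", {
  const <- series_with_x(rep(0.3, 40))
  expect_equal(smooth_series(const, 2)$coords, const$coords, tolerance = 1e-12)

  n <- 101
  v <- rep(0, n); v[51] <- 1
  sm <- smooth_series(series_with_x(v), 2)$coords[, "right_wrist", "x"]
  k <- gaussian_kernel(2)
  r <- (length(k) - 1) / 2
  expect_equal(sm[(51 - r):(51 + r)], as.numeric(k), tolerance = 1e-12)
  expect_equal(sum(k), 1)

  s <- series_with_x(runif(20))
  expect_equal(smooth_series(s, 0)$coords, s$coords)
  expect_error(smooth_series(s, -1), "sigma")
  s$coords[3, "left_hip", "z"] <- NA
  expect_error(smooth_series(s, 2), "interpolate")
})

test_that("position normalization centers the mid-torso every frame", {
  set.seed(21)
  s <- random_skeleton(n = 10)
  np <- normalize_position(s)
  tor <- np$series$coords[, TORSO_LANDMARKS, , drop = FALSE]
  mid <- apply(tor, c(1, 3), mean)
  expect_lt(max(abs(mid)), 1e-12)
  # translation invariance
  s2 <- s; s2$coords <- s$coords + 0.37
  expect_equal(normalize_position(s2)$series$coords, np$series$coords,
               tolerance = 1e-12)
  # a keypoint left of mid-torso (observer view: smaller x) ends negative
  s3 <- s
  s3$coords[, "right_wrist", "x"] <- mid_x <- apply(
    s$coords[, TORSO_LANDMARKS, "x"], 1, mean) - 0.2
  expect_true(all(normalize_position(s3)$series$coords[, "right_wrist", "x"] < 0))
})

test_that("size normalization brings the torso to unit length", {
  set.seed(22)
  s <- random_skeleton(n = 8)
  # rigid torso: same shape translated per frame, so per-frame length is constant
  base <- matrix(runif(12), 4, 3, dimnames = list(TORSO_LANDMARKS, NULL))
  shift <- matrix(runif(8 * 3, -0.05, 0.05), 8, 3)
  for (f in 1:8) s$coords[f, TORSO_LANDMARKS, ] <- base + rep(shift[f, ], each = 4)
  np <- normalize_position(s)
  out <- normalize_size(np$series, np$info)
  ms <- (out$coords[, "left_shoulder", ] + out$coords[, "right_shoulder", ]) / 2
  mh <- (out$coords[, "left_hip", ] + out$coords[, "right_hip", ]) / 2
  expect_equal(sqrt(rowSums((ms - mh)^2)), rep(1, 8), tolerance = 1e-6)
  # scale invariance of the center+scale composition
  s2 <- s; s2$coords <- s$coords * 2
  np2 <- normalize_position(s2)
  expect_equal(normalize_size(np2$series, np2$info)$coords, out$coords,
               tolerance = 1e-9)
  np$info$torso_length <- 0
  expect_error(normalize_size(np$series, np$info), "degenerate")
})

test_that("aspect adjustment scales x only, matching the 16:9 example", {
  s <- series_with_x(c(0, 0.1))
  s$coords[, "right_wrist", "y"] <- c(0.2, 0.4)
  out <- adjust_aspect(s, 16 / 9)
  dx <- diff(out$coords[, "right_wrist", "x"])
  expect_equal(round(dx, 3), 0.178)
  expect_equal(out$coords[, "right_wrist", "y"], s$coords[, "right_wrist", "y"])
  expect_equal(out$coords[, , "z"], s$coords[, , "z"])
  expect_equal(adjust_aspect(s, 1)$coords, s$coords)
  expect_error(adjust_aspect(s, 0), "aspect")
})

test_that("y-inversion is an involution that flips above/below", {
  set.seed(23)
  s <- random_skeleton(n = 5)
  out <- invert_y(s)
  expect_equal(out$coords[, , "y"], -s$coords[, , "y"])
  expect_equal(invert_y(out)$coords, s$coords)
  # above mid-torso = negative y after centering -> positive after inversion
  np <- normalize_position(s)
  above <- np$series$coords[, "left_wrist", "y"] < 0
  inv <- invert_y(np$series)
  expect_equal(inv$coords[, "left_wrist", "y"] > 0, above)
})

test_that("relative fingertips reproduce the worked displacement example", {
  mk <- function(wx, wy, ix, iy) {
    arr <- array(0, c(2, length(CORE_LANDMARKS), 3),
                 dimnames = list(NULL, CORE_LANDMARKS, c("x", "y", "z")))
    arr[, "right_wrist", "x"] <- wx; arr[, "right_wrist", "y"] <- wy
    arr[, "right_index_tip", "x"] <- ix; arr[, "right_index_tip", "y"] <- iy
    skeleton_ts(arr, fps = 30)
  }
  a <- relative_fingertips(mk(1, 1, 1.3, 2.2))
  expect_equal(a$coords[1, "right_index_tip", c("x", "y")],
               c(x = 0.3, y = 1.2))
  # identical hand shape at a different hand position gives identical output
  b <- relative_fingertips(mk(2, 2, 2.3, 3.2))
  expect_equal(b$coords[, "right_index_tip", ],
               a$coords[, "right_index_tip", ])
  # wrist itself is untouched; coincident tip maps to the origin
  expect_equal(a$coords[, "right_wrist", "x"], c(1, 1))
  cc <- relative_fingertips(mk(1, 1, 1, 1))
  expect_equal(unname(cc$coords[1, "right_index_tip", ]), c(0, 0, 0))
})

test_that("the full pipeline equals the manual composition of its steps", {
  set.seed(24)
  s <- random_skeleton(n = 20, na_frac = 0.08)
  cfg <- preprocess_config()
  manual <- interpolate_missing(s)
  manual <- smooth_series(manual, cfg$sigma)
  np <- normalize_position(manual)
  manual <- normalize_size(np$series, np$info)
  manual <- adjust_aspect(manual, cfg$aspect_ratio)
  manual <- invert_y(manual)
  manual <- relative_fingertips(manual)
  out <- run_pipeline(s, cfg)
  expect_equal(out$coords, manual$coords, tolerance = 1e-12)
  expect_false(anyNA(out$coords))
})

test_that("pipeline output is invariant to global translation and scale", {
  set.seed(25)
  s <- random_skeleton(n = 16, na_frac = 0.05)
  ref <- run_pipeline(s)
  shifted <- s; shifted$coords <- s$coords + 0.42
  expect_lt(max(abs(run_pipeline(shifted)$coords - ref$coords)), 1e-9)
  scaled <- s; scaled$coords <- s$coords * 1.9
  expect_lt(max(abs(run_pipeline(scaled)$coords - ref$coords)), 1e-6)
})
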