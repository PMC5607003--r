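test_that("sum projection collapses Z, matching a per-pixel loop oracle", {
  # constant stack: every pixel is Z * value
  a <- array(1, c(2, 31, 4, 4))
  expect_equal(sum_project(a), array(31, c(2, 4, 4)))
  # single nonzero voxel passes through
  b <- array(0, c(1, 5, 3, 3))
  b[1, 4, 2, 3] <- 7
  pb <- sum_project(b)
  expect_equal(pb[1, 2, 3], 7)
  expect_equal(sum(pb), 7)
  # random stacks against the explicit loop
  set.seed(101)
  for (i in 1:5) {
    r <- array(rpois(3 * 4 * 6 * 5, 20), c(3, 4, 6, 5))
    expect_equal(sum_project(r), oracle_sum_project(r))
  }
})

test_that("8-bit conversion implements the floor min-max map", {
  expect_equal(to_8bit(c(0, 510, 1020)), c(0, 127, 255))
  expect_equal(to_8bit(array(5, c(2, 3, 3))), array(0, c(2, 3, 3)))
  set.seed(7)
  v <- runif(1000, -50, 3000)
  out <- to_8bit(v)
  expect_true(all(out >= 0 & out <= 255))
  expect_true(all(out == floor(out)))
  # monotone: order preserved under the map
  o <- order(v)
  expect_true(all(diff(out[o]) >= 0))
})

test_that("registration recovers known translations and matches the oracle", {
  set.seed(33)
  base <- matrix(rpois(40 * 40, 5), 40, 40)
  base[10:13, 20:23] <- 200
  base[30:32, 8:10] <- 150
  mk <- function(frames) image_series(frames, 0.215, 15, 2L)
  # frame translated by (+3, -2) -> recovered shift (-3, +2)
  moved <- fmdestain:::translate_frame(base, 3, -2)
  two <- array(0, c(2, 40, 40))
  two[1, , ] <- base
  two[2, , ] <- moved
  s <- register_series(mk(two), reference_frame = 1, search_radius = 6)
  expect_equal(unname(s$shifts[2, ]), c(-3, 2))
  expect_equal(unname(s$shifts[1, ]), c(0, 0))
  # registered frame equals reference on the overlap
  expect_equal(s$data[2, 1:36, 3:40], base[1:36, 3:40])

  # drift-free series: all shifts zero (idempotence)
  flat <- array(rep(base, 3), c(40, 40, 3))
  flat <- aperm(flat, c(3, 1, 2))
  r0 <- register_series(mk(flat), reference_frame = 2, search_radius = 5)
  expect_true(all(r0$shifts == 0))
  expect_equal(r0$data, flat)
})

test_that("registration equals the exhaustive-search oracle on random drifts", {
  set.seed(91)
  n_cases <- 30
  for (i in seq_len(n_cases)) {
    ref <- matrix(rpois(24 * 24, 3), 24, 24)
    ref[sample(24, 3), sample(24, 3)] <- 120  # structure to lock onto
    d <- c(sample(-4:4, 1), sample(-4:4, 1))
    fr <- fmdestain:::translate_frame(ref, d[1], d[2]) +
      matrix(rnorm(24 * 24, 0, 1), 24, 24)
    w <- fmdestain:::shift_score_matrix(fr, ref, 6)
    impl <- fmdestain:::pick_shift(w)
    orac <- oracle_shift(fr, ref, 6)
    expect_equal(unname(impl), orac)
    expect_equal(orac, d)  # and both recover the truth
  }
})

test_that("oversized search windows are rejected", {
  s <- image_series(array(runif(2 * 10 * 10), c(2, 10, 10)), 1, 15, 2L)
  expect_error(register_series(s, search_radius = 6), "does not fit")
})

test_that("background subtraction picks the frame nearest onset + 180 s", {
  # default 16-frame timeline at 15 s, onset frame 5 (t = 60 s): target
  # 240 s does not exist, the nearest is the last frame (t = 225 s)
  a <- aperm(array(rep(1:16, each = 36), c(6, 6, 16)), c(3, 1, 2))
  s <- image_series(a, 0.215, 15, 5L)
  b <- subtract_background(s)
  expect_equal(b$background_frame, 16L)
  # pixel 50 - ref 30 = 20; pixel 20 - ref 30 clamps to 0
  m <- array(0, c(2, 2, 2))
  m[1, , ] <- 50
  m[2, , ] <- 30
  s2 <- image_series(m, 1, 180, 2L)
  b2 <- subtract_background(s2)
  expect_equal(b2$background_frame, 2L)
  expect_true(all(b2$data[1, , ] == 20))
  expect_true(all(b2$data[2, , ] == 0))
  # ties resolve to the later frame
  expect_equal(nearest_frame_index(c(0, 15, 30), 22.5), 3L)
  # flat puncta stay flat after subtraction
  expect_equal(b2$data[1, , ], b2$data[1, , ])
})

test_that("background subtraction clamps at zero everywhere", {
  set.seed(5)
  a <- array(rpois(10 * 8 * 8, 30), c(10, 8, 8))
  s <- image_series(a, 1, 15, 4L)
  b <- subtract_background(s)
  expect_true(all(b$data >= 0))
  expect_equal(b$data[b$background_frame, , ], matrix(0, 8, 8))
})
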