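mk_series <- function(a, dt = 15, onset = 5L) {
  image_series(a, 0.215, dt, onset)
}

test_that("trace extraction is the per-ROI pixel mean, matching the oracle", {
  set.seed(77)
  # build labelled blobs and a random movie
  f <- matrix(0, 20, 20)
  f[3:5, 3:5] <- 60
  f[12:14, 10:15] <- 60
  rois <- segment_puncta(f, 0.5)
  a <- array(rpois(8 * 20 * 20, 50), c(8, 20, 20))
  s <- mk_series(a, onset = 2L)
  tr <- extract_traces(s, rois)
  for (lb in rois$table$label) {
    expect_equal(unname(tr[, as.character(lb)]),
                 oracle_trace(a, rois$label_image, lb))
  }
  # single-pixel ROI equals that pixel's series
  g <- matrix(0, 20, 20)
  g[7, 9] <- 99
  r1 <- segment_puncta(g, 0.5, area_gate_um2 = c(0, 10))
  expect_equal(unname(extract_traces(s, r1)[, 1]), a[, 7, 9])
  # constant frames give constant traces
  cs <- mk_series(array(3, c(4, 20, 20)), onset = 2L)
  expect_true(all(extract_traces(cs, rois) == 3))
})

test_that("normalization pins the pre-stimulation frame to exactly 1", {
  tr <- c(10, 10, 10, 10, 5, 4, 3)
  nt <- normalize_trace(tr, 5L)
  expect_identical(nt[4], 1)
  expect_equal(nt, c(1, 1, 1, 1, 0.5, 0.4, 0.3))
  # zero or negative reference: exclusion, not division
  bad <- normalize_trace(c(1, 0, 5, 5), 3L)
  expect_true(all(is.na(bad)))
  expect_equal(attr(bad, "reason"), "nonpositive_reference")
})

test_that("responsiveness is strict >5% unloading at the 60 s frame", {
  times <- (0:15) * 15
  onset <- 5L
  base <- rep(1, 16)
  at60 <- nearest_frame_index(times, times[onset] + 60)
  expect_equal(at60, 9L)
  for (case in list(c(0.94, TRUE), c(0.96, FALSE), c(0.95, FALSE))) {
    tr <- base
    tr[at60:16] <- case[1]
    cls <- classify_responsive(tr, times, onset)
    expect_equal(cls$responsive, as.logical(case[2]))
    expect_equal(cls$unloading_frac, 1 - case[1])
    expect_equal(cls$frame_index, at60)
  }
})

test_that("noiseless single-exponential traces are recovered exactly", {
  times <- (0:15) * 15
  onset <- 5L
  t0 <- times[onset]
  for (tau in c(30, 60, 90, 180, 300)) {
    y <- ifelse(times < t0, 1, exp(-(times - t0) / tau))
    fit <- fit_single_exponential(y, times, onset)
    expect_true(fit$converged)
    expect_lt(abs(fit$tau_s - tau) / tau, 0.001)
    expect_lt(abs(fit$amplitude - 1), 0.005)
    expect_lt(abs(fit$plateau), 0.005)
  }
  # free plateau: f = 0.3 + 0.7 exp(-t'/60); also agrees with grid search
  y <- 0.3 + 0.7 * exp(-pmax(0, times - t0) / 60)
  fit <- fit_single_exponential(y, times, onset)
  expect_equal(fit$tau_s, 60, tolerance = 1e-4)
  expect_equal(fit$amplitude, 0.7, tolerance = 1e-4)
  expect_equal(fit$plateau, 0.3, tolerance = 1e-4)
  grid <- oracle_gridfit(y[onset:16], times[onset:16], t0)
  expect_lt(abs(fit$tau_s - grid$tau), 1)      # grid resolution 1 s
  expect_lt(abs(fit$amplitude - grid$A), 0.01)
  expect_lt(abs(fit$plateau - grid$C), 0.01)
})

test_that("degenerate fits fail loudly, flat traces yield no tau", {
  times <- (0:15) * 15
  flat <- rep(1, 16)
  fit <- fit_single_exponential(flat, times, 5L)
  expect_false(fit$converged)
  expect_true(is.na(fit$tau_s))
  expect_error(fit_single_exponential(rep(1, 6), (0:5) * 15, 4L),
               "at least 4")
})

test_that("tau exclusion is a monotone threshold rule", {
  res <- data.frame(punctum_id = 1:5,
                    tau_s = c(90, 360, 360.001, 400, NA))
  out <- apply_tau_exclusion(res)
  expect_equal(out$included, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # 400 s is excluded under both candidate readings of the ceiling
  expect_false(apply_tau_exclusion(res, 180)$included[4])
  # nested inclusion: stricter ceiling keeps a subset
  in180 <- apply_tau_exclusion(res, 180)$included
  in360 <- apply_tau_exclusion(res, 360)$included
  expect_true(all(!in180 | in360))
})

test_that("classification is identical with and without background subtraction", {
  cfg <- tiny_config(rng_seed = 9L)
  ex <- simulate_experiment(cfg)
  reg <- register_series(to_8bit(sum_project(ex$fm_stack)))
  bg <- subtract_background(reg)
  rois <- segment_puncta(reg$data[1, , ], cfg$pixel_size_um)
  k1 <- analyze_kinetics(reg, rois, bgsub_series = bg, fit_trace = "raw")
  k2 <- analyze_kinetics(reg, rois, bgsub_series = NULL, fit_trace = "raw")
  expect_identical(k1$results$responsive, k2$results$responsive)
  expect_identical(k1$results$unloading_frac_60s,
                   k2$results$unloading_frac_60s)
})

test_that("field summary counts, percentages and mean curve are consistent", {
  cfg <- tiny_config(n_responsive = 7L, n_unresponsive = 3L,
                     shot_noise = FALSE, read_noise_sd = 0,
                     drift_step_px = 0L, rng_seed = 21L)
  ex <- simulate_experiment(cfg)
  an <- run_analysis(ex)
  s <- an$summary
  expect_equal(s$n_responsive, 7L)
  expect_equal(s$n_unresponsive, 3L)
  expect_equal(s$pct_responsive, 70)
  expect_equal(s$n_puncta_total, 10L)
  expect_equal(s$mean_curve$n[1], 7L)
  expect_equal(s$mean_curve$mean[an$kinetics$stim_onset_frame - 1], 1)
})

test_that("mean curve of a homogeneous-tau population follows the model", {
  cfg <- tiny_config(n_responsive = 8L, n_unresponsive = 0L,
                     tau_mean_s = 90, tau_sd_s = 0,
                     residual_fraction_range = c(0.1, 0.1),
                     drift_step_px = 0L, rng_seed = 31L)
  ex <- simulate_experiment(cfg)
  an <- run_analysis(ex)
  mc <- an$summary$mean_curve
  onset <- an$kinetics$stim_onset_frame
  tprime <- pmax(0, mc$time_s - mc$time_s[onset])
  # raw normalized curve: (B + A(r + (1-r) e^{-t'/tau})) / (B + A); with
  # B << A this is approximately r + (1-r) e^{-t'/tau}
  model <- 0.1 + 0.9 * exp(-tprime / 90)
  expect_lt(max(abs(mc$mean - model)), 0.03)
})
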