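test_that("simulator bookkeeping: counts, flags, timeline, drift shape", {
  # a 30 + 10 punctum field needs the full-size default field to respect the
  # centre separation on the dendrite mask
  cfg <- tiny_config(n_responsive = 30L, n_unresponsive = 10L,
                     field_shape_px = c(192L, 192L), n_dendrites = 3L)
  ex <- simulate_experiment(cfg)
  expect_equal(nrow(ex$truth), 40L)
  expect_equal(sum(ex$truth$responsive), 30L)
  expect_true(all(is.na(ex$truth$tau_true_s[!ex$truth$responsive])))
  expect_true(all(ex$truth$tau_true_s[ex$truth$responsive] > 0))
  expect_true(all(ex$truth$residual_fraction >= 0 &
                  ex$truth$residual_fraction < 1))
  nt <- cfg$n_baseline_frames + cfg$n_stim_frames + cfg$n_post_frames
  expect_equal(dim(ex$fm_stack$data)[1], nt)
  expect_equal(nrow(ex$applied_drift), nt)
  expect_equal(unname(ex$applied_drift[1, ]), c(0L, 0L))
  expect_true(all(abs(ex$applied_drift) <= cfg$drift_max_px))
  expect_equal(ex$fm_stack$stim_onset_frame, cfg$n_baseline_frames + 1L)
})

test_that("identical config + seed gives bit-identical output", {
  cfg <- tiny_config(marker_positive_frac = c(vglut1 = 0.8))
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$fm_stack$data, b$fm_stack$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$egfp_image, b$egfp_image)
  expect_identical(a$marker_images, b$marker_images)
  c2 <- simulate_experiment(tiny_config(rng_seed = 43L))
  expect_false(identical(a$fm_stack$data, c2$fm_stack$data))
})

test_that("noiseless responsive punctum is exactly mono-exponential after onset", {
  cfg <- clean_config()
  ex <- simulate_experiment(cfg)
  proj <- sum_project(ex$fm_stack)
  py <- round(ex$truth$y_px)
  px <- round(ex$truth$x_px)
  trace <- proj$data[, py, px]
  times <- frame_times(proj)
  onset <- proj$stim_onset_frame
  t_stim <- times[onset]
  bg <- cfg$n_z * cfg$background_level
  peak <- trace[1] - bg
  expected <- bg + peak * exp(-pmax(0, times - t_stim) / 90)
  expect_equal(trace, expected, tolerance = 1e-10)
  # monotone non-increasing after onset, constant before
  expect_true(all(diff(trace[onset:length(trace)]) <= 1e-9))
  expect_equal(trace[1:(onset - 1)], rep(trace[1], onset - 1))
})

test_that("noise/drift off: total intensity conserved before stimulation", {
  cfg <- tiny_config(shot_noise = FALSE, read_noise_sd = 0, drift_step_px = 0L)
  ex <- simulate_experiment(cfg)
  proj <- sum_project(ex$fm_stack)
  totals <- apply(proj$data, 1, sum)
  onset <- proj$stim_onset_frame
  expect_equal(totals[1:(onset - 1)], rep(totals[1], onset - 1),
               tolerance = 1e-12)
  # and decreases afterwards (responsive puncta unload)
  expect_lt(totals[length(totals)], totals[1])
})

test_that("frac_on_dendrite places punctum centres on/off the eGFP mask", {
  for (f in c(0, 1)) {
    cfg <- tiny_config(frac_on_dendrite = f, rng_seed = 11L)
    ex <- simulate_experiment(cfg)
    pix <- cbind(round(ex$truth$y_px), round(ex$truth$x_px))
    inside <- ex$egfp_mask[pix]
    if (f == 1) expect_true(all(inside)) else expect_true(!any(inside))
    expect_equal(ex$truth$on_dendrite, unname(inside))
  }
})

test_that("eGFP mask area fraction is a plausible dendritic arbor", {
  for (s in 1:5) {
    cfg <- sim_config(rng_seed = s)
    m <- simulate_egfp_channel(cfg)
    frac <- mean(m$mask)
    expect_gt(frac, 0.01)
    expect_lt(frac, 0.30)
    # mask must contain its own skeleton
    expect_true(all(m$mask[m$skeleton]))
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(tau_mean_s = -1))
  expect_error(sim_config(n_baseline_frames = 0L))
  expect_error(sim_config(pixel_size_um = 0))
  expect_error(sim_config(residual_fraction_range = c(0, 1)))
  # field too small for the margin
  cfg <- tiny_config(field_shape_px = c(20L, 20L), edge_margin_px = 10L)
  expect_error(simulate_experiment(cfg), "degenerate")
})

test_that("experiment round-trips through write_experiment / read_experiment", {
  cfg <- tiny_config(marker_positive_frac = c(vglut1 = 0.8))
  ex <- simulate_experiment(cfg)
  d <- withr::local_tempdir()
  write_experiment(ex, d)
  back <- read_experiment(d)
  expect_equal(back$fm_stack$data,
               pmin(pmax(round(ex$fm_stack$data), 0), 65535))
  expect_equal(back$truth$y_px, ex$truth$y_px)
  expect_equal(back$applied_drift, ex$applied_drift)
  expect_equal(back$fm_stack$stim_onset_frame, ex$fm_stack$stim_onset_frame)
  expect_named(back$marker_images, "vglut1")
})
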