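test_that("labelling matches a flood-fill oracle on random binary images", {
  set.seed(202)
  for (i in 1:30) {
    fg <- matrix(runif(18 * 15) < 0.35, 18, 15)
    impl <- label_components(fg)
    orac <- oracle_label(fg)
    # same partition: label images must be identical up to renumbering;
    # both number components in raster order, so they are equal outright
    expect_identical(impl, orac)
  }
  # diagonal touch is one component (8-connectivity)
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- m[2, 2] <- TRUE
  expect_equal(max(label_components(m)), 1L)
})

test_that("segmentation applies the inclusive threshold and the area gate", {
  expect_equal(nrow(segment_puncta(matrix(0, 10, 10), 0.215)$table), 0L)

  # a 5-px spot (0.23 um^2 at 0.215 um/px) fails the gate; 50 px passes
  f <- matrix(0, 30, 30)
  f[5, 5:9] <- 20
  f[15:19, 10:19] <- 20   # 50 px
  rois <- segment_puncta(f, 0.215)
  tab <- rois$table[order(tab_area <- rois$table$n_pixels), ]
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_pixels, c(5L, 50L))
  expect_equal(tab$area_um2, c(5, 50) * 0.215^2)
  expect_equal(tab$in_gate, c(FALSE, TRUE))

  # threshold is inclusive: a pixel exactly at 15 is foreground
  g <- matrix(0, 8, 8)
  g[3:6, 3:6] <- 15
  expect_equal(sum(segment_puncta(g, 1)$label_image > 0), 16L)
  g[3:6, 3:6] <- 14.999
  expect_equal(nrow(segment_puncta(g, 1)$table), 0L)

  # boundary areas: 0.4 and 10 um^2 are inside the gate (inclusive)
  px1um <- 1  # 1 um pixels for round numbers
  h <- matrix(0, 30, 30)
  h[1, 1] <- 20                       # 1 px = 1 um^2, in gate
  h[10:11, 10:14] <- 20               # 10 px = 10 um^2, in gate
  h[20:22, 20:23] <- 20               # 12 px = 12 um^2, out
  tab <- segment_puncta(h, px1um)$table
  expect_equal(tab$in_gate[order(tab$n_pixels)], c(TRUE, TRUE, FALSE))
})

test_that("eGFP mask recovery: threshold + dilation covers the truth", {
  cfg <- tiny_config(rng_seed = 3L)
  ch <- simulate_egfp_channel(cfg)
  em <- build_egfp_mask(ch$image, dilation_px = 2L)
  # recovered mask must contain the true skeleton and nearly all of the mask
  expect_true(all(em$mask[ch$skeleton]))
  expect_gt(mean(em$mask[ch$mask]), 0.98)
  # dilation is monotone
  m0 <- build_egfp_mask(ch$image, dilation_px = 0L)
  expect_true(all(em$mask[m0$mask]))
  # constant image -> empty mask with a warning
  expect_warning(e0 <- build_egfp_mask(matrix(1, 10, 10)), "constant")
  expect_false(any(e0$mask))
})

test_that("mask assignment is centroid-in-mask, matching direct lookup", {
  set.seed(55)
  f <- matrix(0, 40, 40)
  centers <- cbind(sample(5:35, 6), sample(5:35, 6))
  for (k in 1:6) {
    f[centers[k, 1] + (-1:1), centers[k, 2] + (-1:1)] <- 50
  }
  rois <- segment_puncta(f, 0.5)
  mask <- matrix(FALSE, 40, 40)
  mask[, 1:20] <- TRUE
  out <- assign_to_mask(rois, mask)
  expect_equal(out$table$on_mask,
               mask[cbind(round(out$table$centroid_y),
                          round(out$table$centroid_x))])
  # empty mask -> none assigned
  none <- assign_to_mask(rois, matrix(FALSE, 40, 40))
  expect_false(any(none$table$on_mask))
})

test_that("marker fractions: identity and blank channels are exact", {
  f <- matrix(0, 40, 40)
  f[10:13, 10:13] <- 200
  f[25:28, 30:33] <- 255   # ensures the 8-bit range is the identity map
  rois <- segment_puncta(f, 0.5)
  expect_equal(marker_positive_fraction(rois, f)$fraction, 1.0)
  expect_equal(marker_positive_fraction(rois, matrix(0, 40, 40))$fraction, 0.0)
  # no in-gate puncta -> NA with a warning
  tiny <- matrix(0, 40, 40)
  tiny[5, 5] <- 200
  r2 <- segment_puncta(tiny, 0.215)
  expect_warning(out <- marker_positive_fraction(r2, tiny), "undefined")
  expect_true(is.na(out$fraction))
})

test_that("simulated marker channel recovers the configured positive fraction", {
  cfg <- sim_config(n_responsive = 40L, n_unresponsive = 10L,
                    n_z = 3L, drift_step_px = 0L,
                    marker_positive_frac = c(vglut1 = 0.8), rng_seed = 12L)
  ex <- simulate_experiment(cfg)
  an <- run_analysis(ex)
  frac <- an$marker_fractions[["vglut1"]]
  n <- sum(an$rois$table$in_gate)
  ci <- qbinom(c(0.025, 0.975), n, 0.8) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  # flags agree with ground truth for matched puncta
  seg <- evaluate_segmentation(an, ex,
                               drift_ref_yx = ex$applied_drift[an$reference_frame, ])
  j <- merge(seg$matches, ex$truth, by.x = "truth_id", by.y = "id")
  j <- merge(j, an$rois$table, by = "label")
  expect_gt(mean(j$marker_vglut1.x == j$marker_vglut1.y), 0.9)
})
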