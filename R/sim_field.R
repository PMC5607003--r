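# Synthetic FM destaining experiments with exhaustive ground truth.
#
# The simulator emulates the acquisition protocol the analysis pipeline is
# built for: a confocal z-stack captured every 15 s over a 1 min baseline,
# 1 min stimulation and 2 min post-stimulation period, with puncta that
# either destain mono-exponentially after stimulation onset (responsive) or
# stay flat (unresponsive), additive background, Poisson shot noise plus
# Gaussian read noise, bounded rigid stage drift, and an eGFP dendrite
# channel on which a configurable fraction of puncta lie.

#' Simulation configuration
#'
#' Defaults mirror the acquisition this pipeline targets: 31-slice z-stacks
#' at 15 s cadence (4 baseline + 4 stimulation + 8 post frames), 0.215 um
#' pixels (a 60x objective with 2x2 binning). True decay constants are drawn
#' lognormal with mean `tau_mean_s` and standard deviation `tau_sd_s`;
#' defaults are an uninjured-control-like population (mean 124.8 s,
#' sd 79.7 s). Stimulation parameters are carried as an annotation only;
#' no electrical model is simulated.
#'
#' @param field_shape_px `(height, width)` in pixels.
#' @param n_z z-slices per timepoint.
#' @param pixel_size_um pixel edge length (um).
#' @param frame_interval_s seconds between frames.
#' @param n_baseline_frames,n_stim_frames,n_post_frames timeline (frames).
#' @param n_responsive,n_unresponsive punctum counts.
#' @param tau_mean_s,tau_sd_s mean and sd of the lognormal true-tau
#'   distribution (s).
#' @param punctum_amplitude_range peak punctum intensity, uniform draw.
#' @param punctum_sigma_um Gaussian spot width (um).
#' @param residual_fraction_range per-punctum plateau after full unloading,
#'   uniform draw in `[0, 1)`.
#' @param background_level per-slice background intensity.
#' @param read_noise_sd per-slice Gaussian read noise sd.
#' @param shot_noise apply Poisson noise to each voxel.
#' @param drift_step_px maximum per-frame rigid drift step (0 disables).
#' @param drift_max_px cumulative drift bound.
#' @param bleach_tau_s global photobleaching time constant (0 = off).
#' @param frac_on_dendrite fraction of puncta whose centres lie on the eGFP
#'   dendrite mask.
#' @param n_dendrites,dendrite_width_um eGFP dendrite geometry.
#' @param marker_positive_frac named numeric vector: per marker channel, the
#'   probability that an FM punctum is marker-positive (NULL = no markers).
#' @param marker_extra_foci_frac marker foci not at FM puncta, as a fraction
#'   of punctum count.
#' @param min_separation_um minimum distance between punctum centres.
#' @param edge_margin_px keep punctum centres this far from the field edge.
#' @param stim_annotation free-text stimulation metadata (annotation only).
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return Class `fm_sim_config` (a validated named list).
#' @export
sim_config <- function(field_shape_px = c(192L, 192L),
                       n_z = 31L,
                       pixel_size_um = 0.215,
                       frame_interval_s = 15,
                       n_baseline_frames = 4L,
                       n_stim_frames = 4L,
                       n_post_frames = 8L,
                       n_responsive = 30L,
                       n_unresponsive = 10L,
                       tau_mean_s = 124.8,
                       tau_sd_s = 79.7,
                       punctum_amplitude_range = c(600, 1200),
                       punctum_sigma_um = 0.3,
                       residual_fraction_range = c(0.05, 0.2),
                       background_level = 0.2,
                       read_noise_sd = 0.5,
                       shot_noise = TRUE,
                       drift_step_px = 1L,
                       drift_max_px = 6L,
                       bleach_tau_s = 0,
                       frac_on_dendrite = 0.6,
                       n_dendrites = 3L,
                       dendrite_width_um = 2,
                       marker_positive_frac = NULL,
                       marker_extra_foci_frac = 0.2,
                       min_separation_um = 2,
                       edge_margin_px = 12L,
                       stim_annotation = "20 Hz, 600 pulses, ~1 min",
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$field_shape_px) == 2L, all(cfg$field_shape_px >= 16),
            cfg$n_z >= 1, cfg$pixel_size_um > 0, cfg$frame_interval_s > 0,
            cfg$n_baseline_frames >= 1, cfg$n_stim_frames >= 0,
            cfg$n_post_frames >= 0,
            cfg$n_responsive >= 0, cfg$n_unresponsive >= 0,
            cfg$tau_mean_s > 0, cfg$tau_sd_s >= 0,
            length(cfg$punctum_amplitude_range) == 2L,
            all(cfg$punctum_amplitude_range > 0),
            diff(cfg$punctum_amplitude_range) >= 0,
            cfg$punctum_sigma_um > 0,
            all(cfg$residual_fraction_range >= 0),
            all(cfg$residual_fraction_range < 1),
            cfg$background_level >= 0, cfg$read_noise_sd >= 0,
            cfg$drift_step_px >= 0, cfg$drift_max_px >= cfg$drift_step_px,
            cfg$bleach_tau_s >= 0,
            cfg$frac_on_dendrite >= 0, cfg$frac_on_dendrite <= 1,
            cfg$min_separation_um >= 0, cfg$edge_margin_px >= 0)
  if (!is.null(cfg$marker_positive_frac)) {
    stopifnot(is.numeric(cfg$marker_positive_frac),
              !is.null(names(cfg$marker_positive_frac)),
              all(cfg$marker_positive_frac >= 0),
              all(cfg$marker_positive_frac <= 1))
  }
  structure(cfg, class = "fm_sim_config")
}

#' Decay-constant presets for the two reference conditions
#'
#' Lognormal (mean, sd) pairs for simulating an uninjured-control-like or an
#' axotomy-like punctum population at 48 h (mean decay constants 124.8 s and
#' 78.65 s; spreads reconstructed from the corresponding standard errors and
#' punctum counts, 5.487 x sqrt(211) and 3.922 x sqrt(304)).
#'
#' @param condition `"control_48h"` or `"axotomy_48h"`.
#' @return List with `tau_mean_s` and `tau_sd_s`.
#' @export
tau_preset <- function(condition = c("control_48h", "axotomy_48h")) {
  condition <- match.arg(condition)
  switch(condition,
         control_48h = list(tau_mean_s = 124.8,
                            tau_sd_s = 5.487 * sqrt(211)),
         axotomy_48h = list(tau_mean_s = 78.65,
                            tau_sd_s = 3.922 * sqrt(304)))
}

# lognormal parameterization from mean/sd on the natural scale
lnorm_params <- function(m, s) {
  if (s <= 0) return(list(meanlog = log(m), sdlog = 0))
  v <- log(1 + (s / m)^2)
  list(meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

# Render 2-D Gaussian spots integrated per pixel; `centers` is an n x 2
# matrix (y, x) in pixel coordinates, `amp` the per-spot peak scale.
render_spots <- function(shape, centers, amp, sigma_px) {
  img <- matrix(0, shape[1], shape[2])
  if (!nrow(centers)) return(img)
  w <- ceiling(4 * sigma_px)
  norm <- 2 * pi * sigma_px^2
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]
    cx <- centers[i, 2]
    ys <- max(1, floor(cy) - w):min(shape[1], ceiling(cy) + w)
    xs <- max(1, floor(cx) - w):min(shape[2], ceiling(cx) + w)
    if (!length(ys) || !length(xs)) next
    gy <- pnorm((ys + 0.5 - cy) / sigma_px) - pnorm((ys - 0.5 - cy) / sigma_px)
    gx <- pnorm((xs + 0.5 - cx) / sigma_px) - pnorm((xs - 0.5 - cx) / sigma_px)
    img[ys, xs] <- img[ys, xs] + amp[i] * norm * outer(gy, gx)
  }
  img
}

# Dendrite skeleton + mask + rendered eGFP image (no RNG seeding here; the
# exported wrapper and simulate_experiment control the seed).
sim_egfp <- function(config) {
  shape <- config$field_shape_px
  ny <- shape[1]
  nx <- shape[2]
  skel <- matrix(FALSE, ny, nx)
  spine_px <- matrix(FALSE, ny, nx)
  put <- function(m, y, x) {
    ok <- y >= 1 & y <= ny & x >= 1 & x <= nx
    m[cbind(y[ok], x[ok])] <- TRUE
    m
  }
  for (d in seq_len(config$n_dendrites)) {
    # start on a random edge, head inwards, wander in bounded-angle segments
    side <- sample(4L, 1L)
    pos <- switch(side,
                  c(1, runif(1, 1, nx)),
                  c(ny, runif(1, 1, nx)),
                  c(runif(1, 1, ny), 1),
                  c(runif(1, 1, ny), nx))
    ang <- switch(side,
                  runif(1, pi / 4, 3 * pi / 4),
                  runif(1, -3 * pi / 4, -pi / 4),
                  runif(1, -pi / 4, pi / 4),
                  runif(1, 3 * pi / 4, 5 * pi / 4))
    for (s in seq_len(4L)) {
      len <- runif(1, 25, 50)
      tt <- seq(0, len, by = 0.5)
      yy <- round(pos[1] + tt * sin(ang))
      xx <- round(pos[2] + tt * cos(ang))
      skel <- put(skel, yy, xx)
      # spine-like protrusions every few microns
      n_sp <- max(1L, round(len / um_to_px(4, config$pixel_size_um)))
      for (k in seq_len(n_sp)) {
        t0 <- runif(1, 0, len)
        perp <- ang + sample(c(-1, 1), 1) * pi / 2
        sl <- runif(1, 3, 6)
        st <- seq(0, sl, by = 0.5)
        spine_px <- put(spine_px,
                        round(pos[1] + t0 * sin(ang) + st * sin(perp)),
                        round(pos[2] + t0 * cos(ang) + st * cos(perp)))
      }
      pos <- pos + len * c(sin(ang), cos(ang))
      # bounce off the field edges so dendrites keep their full length
      if (pos[1] < 1 || pos[1] > ny) {
        ang <- -ang
        pos[1] <- min(max(pos[1], 1), ny)
      }
      if (pos[2] < 1 || pos[2] > nx) {
        ang <- pi - ang
        pos[2] <- min(max(pos[2], 1), nx)
      }
      ang <- ang + runif(1, -0.6, 0.6)
    }
  }
  half_w <- max(1L, round(um_to_px(config$dendrite_width_um / 2,
                                   config$pixel_size_um)))
  dil <- function(m, r) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    matrix(as.logical(EBImage::dilate(EBImage::Image(m * 1), brush) > 0.5),
           ny, nx)
  }
  mask <- dil(skel, half_w) | dil(spine_px, 1L)
  image <- 150 * mask + 5 + matrix(rnorm(ny * nx, 0, 2), ny, nx)
  list(image = image, mask = mask, skeleton = skel)
}

#' Simulate the eGFP dendrite channel
#'
#' Piecewise-linear dendrite skeletons dilated to the configured width with
#' small spine-like protrusions, rendered at high contrast over a dim noisy
#' background.
#'
#' @param config an `fm_sim_config`.
#' @return List: `image` (numeric matrix), `mask` (logical ground-truth
#'   mask), `skeleton` (logical).
#' @export
simulate_egfp_channel <- function(config) {
  stopifnot(inherits(config, "fm_sim_config"))
  withr::with_seed(config$rng_seed, sim_egfp(config))
}

# Rejection-sample punctum centres with a minimum separation, optionally
# constrained to lie on / off a mask.
place_centers <- function(n, shape, margin, min_sep_px, mask, on_mask) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  ny <- shape[1]
  nx <- shape[2]
  ok_y <- (margin + 1):(ny - margin)
  ok_x <- (margin + 1):(nx - margin)
  if (length(ok_y) < 1L || length(ok_x) < 1L) {
    stop("field too small for the configured edge margin")
  }
  interior <- matrix(FALSE, ny, nx)
  interior[ok_y, ok_x] <- TRUE
  pool_on <- which(mask & interior)
  pool_off <- which(!mask & interior)
  centers <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 50000L) {
      stop("degenerate field: cannot place ", n, " puncta with ",
           "the configured separation and margin")
    }
    want_on <- on_mask[placed + 1L]
    pool <- if (want_on) pool_on else pool_off
    if (!length(pool)) {
      stop("degenerate field: no ", if (want_on) "mask" else "background",
           " pixels available for punctum placement")
    }
    px <- pool[sample.int(length(pool), 1L)]
    y <- ((px - 1L) %% ny) + 1L + runif(1, -0.45, 0.45)
    x <- ((px - 1L) %/% ny) + 1L + runif(1, -0.45, 0.45)
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - y)^2 +
            (centers[seq_len(placed), 2] - x)^2
      if (min(d2) < min_sep_px^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(y, x)
  }
  centers
}

#' Simulate a complete FM destaining experiment
#'
#' Responsive puncta follow, before noise and drift,
#' `I(t) = B + A * (r + (1 - r) * exp(-max(0, t - t_stim) / tau))`
#' per punctum; unresponsive puncta stay at `B + A`. Drift is a bounded
#' integer random walk applied as a whole-frame translation; noise is
#' optional per-voxel Poisson (shot) plus Gaussian (read) noise; the z
#' dimension spreads each spot across slices so that sum projection recovers
#' the 2-D model exactly.
#'
#' @param config an `fm_sim_config`.
#' @return Class `fm_experiment`: list with `fm_stack` (an [image_series()],
#'   `T x Z x Y x X`), `egfp_image`, `egfp_mask`, `marker_images` (named
#'   list), `truth` (data frame: `id`, `y_px`, `x_px` (frame-1 scene
#'   coordinates), `amplitude`, `responsive`, `tau_true_s`,
#'   `residual_fraction`, `area_um2`, `in_gate`, `on_dendrite`, one
#'   `marker_*` column per channel), `applied_drift` (`T x 2`, first row
#'   `(0, 0)`), `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "fm_sim_config"))
  withr::with_seed(config$rng_seed, {
    shape <- config$field_shape_px
    nt <- config$n_baseline_frames + config$n_stim_frames +
      config$n_post_frames
    stopifnot(nt >= 2)
    n <- config$n_responsive + config$n_unresponsive
    sigma_px <- um_to_px(config$punctum_sigma_um, config$pixel_size_um)
    min_sep_px <- um_to_px(config$min_separation_um, config$pixel_size_um)
    if (2 * config$edge_margin_px + 2 >= min(shape)) {
      stop("degenerate field: margin leaves no interior")
    }

    egfp <- sim_egfp(config)

    on_dendrite <- rep(FALSE, n)
    if (n > 0L) {
      on_dendrite[sample.int(n, round(config$frac_on_dendrite * n))] <- TRUE
    }
    centers <- place_centers(n, shape, config$edge_margin_px, min_sep_px,
                             egfp$mask, on_dendrite)

    responsive <- rep(c(TRUE, FALSE),
                      c(config$n_responsive, config$n_unresponsive))
    amp <- runif(n, config$punctum_amplitude_range[1],
                 config$punctum_amplitude_range[2])
    lp <- lnorm_params(config$tau_mean_s, config$tau_sd_s)
    tau <- ifelse(responsive,
                  rlnorm(n, lp$meanlog, lp$sdlog), NA_real_)
    resid_frac <- runif(n, config$residual_fraction_range[1],
                        config$residual_fraction_range[2])

    truth <- data.frame(
      id = seq_len(n),
      y_px = centers[, 1], x_px = centers[, 2],
      amplitude = amp, responsive = responsive, tau_true_s = tau,
      residual_fraction = resid_frac,
      area_um2 = pi * (2 * config$punctum_sigma_um)^2,
      in_gate = TRUE,
      on_dendrite = on_dendrite)

    marker_images <- list()
    if (!is.null(config$marker_positive_frac)) {
      for (mk in names(config$marker_positive_frac)) {
        f <- config$marker_positive_frac[[mk]]
        flag <- runif(n) < f
        truth[[paste0("marker_", mk)]] <- flag
        mk_centers <- centers[flag, , drop = FALSE]
        n_extra <- round(config$marker_extra_foci_frac * n)
        if (n_extra > 0L) {
          all_cent <- rbind(centers, matrix(NA_real_, n_extra, 2L))
          k <- n
          tries <- 0L
          while (k < n + n_extra && tries < 20000L) {
            tries <- tries + 1L
            y <- runif(1, config$edge_margin_px + 1,
                       shape[1] - config$edge_margin_px)
            x <- runif(1, config$edge_margin_px + 1,
                       shape[2] - config$edge_margin_px)
            d2 <- (all_cent[seq_len(k), 1] - y)^2 +
                  (all_cent[seq_len(k), 2] - x)^2
            if (min(d2) < min_sep_px^2) next
            k <- k + 1L
            all_cent[k, ] <- c(y, x)
          }
          mk_centers <- rbind(mk_centers,
                              all_cent[(n + 1):k, , drop = FALSE])
        }
        mk_amp <- runif(nrow(mk_centers), config$punctum_amplitude_range[1],
                        config$punctum_amplitude_range[2])
        img <- render_spots(shape, mk_centers, mk_amp, sigma_px) + 2 +
          matrix(rnorm(prod(shape), 0, config$read_noise_sd),
                 shape[1], shape[2])
        marker_images[[mk]] <- img
      }
    }

    # bounded integer random-walk drift; frame 1 has none
    drift <- matrix(0L, nt, 2L, dimnames = list(NULL, c("dy", "dx")))
    s <- config$drift_step_px
    if (s > 0) {
      for (t in 2:nt) {
        step <- c(sample(-s:s, 1L), sample(-s:s, 1L))
        drift[t, ] <- pmin(pmax(drift[t - 1L, ] + step,
                                -config$drift_max_px), config$drift_max_px)
      }
    }

    times <- (seq_len(nt) - 1) * config$frame_interval_s
    t_stim <- (config$n_baseline_frames) * config$frame_interval_s
    # z profile: Gaussian spread across slices, normalized so the sum
    # projection recovers the 2-D model exactly
    zc <- (config$n_z + 1) / 2
    wz <- exp(-((seq_len(config$n_z) - zc)^2) / (2 * (config$n_z / 4)^2))
    wz <- wz / sum(wz)

    stack <- array(0, c(nt, config$n_z, shape[1], shape[2]))
    for (t in seq_len(nt)) {
      dt <- pmax(0, times[t] - t_stim)
      a_t <- ifelse(responsive,
                    amp * (resid_frac + (1 - resid_frac) * exp(-dt / tau)),
                    amp)
      if (config$bleach_tau_s > 0) {
        a_t <- a_t * exp(-times[t] / config$bleach_tau_s)
      }
      ctr <- centers
      ctr[, 1] <- ctr[, 1] + drift[t, 1]
      ctr[, 2] <- ctr[, 2] + drift[t, 2]
      sig <- render_spots(shape, ctr, a_t, sigma_px)
      for (z in seq_len(config$n_z)) {
        lam <- wz[z] * sig + config$background_level
        v <- if (config$shot_noise) {
          rpois(length(lam), lam)
        } else {
          lam
        }
        if (config$read_noise_sd > 0) {
          v <- v + rnorm(length(lam), 0, config$read_noise_sd)
        }
        stack[t, z, , ] <- v
      }
    }

    fm_stack <- image_series(stack, config$pixel_size_um,
                             config$frame_interval_s,
                             config$n_baseline_frames + 1L)
    structure(list(fm_stack = fm_stack,
                   egfp_image = egfp$image,
                   egfp_mask = egfp$mask,
                   marker_images = marker_images,
                   truth = truth,
                   applied_drift = drift,
                   config = config),
              class = "fm_experiment")
  })
}

#' @export
print.fm_experiment <- function(x, ...) {
  cat(sprintf(
    "<fm_experiment> %d puncta (%d responsive), %d frames, %d z-slices, seed %d\n",
    nrow(x$truth), sum(x$truth$responsive), dim(x$fm_stack$data)[1],
    x$config$n_z, x$config$rng_seed))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes one multi-page TIFF per channel, a CSV truth table, and a JSON
#' sidecar (config echo, applied drift, acquisition constants) that doubles
#' as the experiment manifest for [read_experiment()] and [run_analysis()].
#'
#' @param experiment an `fm_experiment`.
#' @param out_dir output directory (created if needed).
#' @return Path of the JSON sidecar, invisibly.
#' @export
write_experiment <- function(experiment, out_dir) {
  stopifnot(inherits(experiment, "fm_experiment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clamp16 <- function(a) pmin(pmax(round(a), 0), 65535)
  write_stack(clamp16(experiment$fm_stack$data),
              file.path(out_dir, "fm.tif"))
  write_stack(clamp16(experiment$egfp_image),
              file.path(out_dir, "egfp.tif"))
  for (mk in names(experiment$marker_images)) {
    write_stack(clamp16(experiment$marker_images[[mk]]),
                file.path(out_dir, paste0("marker_", mk, ".tif")))
  }
  write.csv(experiment$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE)
  cfg <- experiment$config
  sidecar <- list(
    fm_stack = "fm.tif",
    egfp_image = "egfp.tif",
    marker_images = as.list(setNames(
      paste0("marker_", names(experiment$marker_images), ".tif"),
      names(experiment$marker_images))),
    truth = "truth.csv",
    n_z = cfg$n_z,
    pixel_size_um = cfg$pixel_size_um,
    frame_interval_s = cfg$frame_interval_s,
    stim_onset_frame = cfg$n_baseline_frames + 1L,
    applied_drift = experiment$applied_drift,
    config = unclass(cfg))
  p <- file.path(out_dir, "experiment.json")
  jsonlite::write_json(sidecar, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}

#' Read back a simulated experiment written by [write_experiment()]
#'
#' @param dir directory containing `experiment.json`.
#' @return An `fm_experiment` (image data quantized to 16-bit integers).
#' @export
read_experiment <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "experiment.json"),
                              simplifyVector = TRUE)
  fm <- load_stack(file.path(dir, side$fm_stack), n_z = side$n_z,
                   pixel_size_um = side$pixel_size_um,
                   frame_interval_s = side$frame_interval_s,
                   stim_onset_frame = side$stim_onset_frame)
  egfp <- tiff::readTIFF(file.path(dir, side$egfp_image), as.is = TRUE)
  markers <- list()
  for (mk in names(side$marker_images)) {
    markers[[mk]] <- tiff::readTIFF(file.path(dir, side$marker_images[[mk]]),
                                    as.is = TRUE)
  }
  truth <- read.csv(file.path(dir, side$truth))
  cfg <- side$config
  cfg$field_shape_px <- as.integer(cfg$field_shape_px)
  structure(list(fm_stack = fm,
                 egfp_image = egfp,
                 egfp_mask = NULL,
                 marker_images = markers,
                 truth = truth,
                 applied_drift = matrix(as.integer(side$applied_drift),
                                        ncol = 2L,
                                        dimnames = list(NULL, c("dy", "dx"))),
                 config = cfg),
            class = "fm_experiment")
}
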