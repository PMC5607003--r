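# Orchestration: project -> 8-bit -> register -> (raw | background-
# subtracted) -> segment -> mask-assign -> traces -> classify -> fit ->
# exclude -> summarize.

#' Analysis parameters
#'
#' Every tunable of the pipeline in one validated, serializable object,
#' echoed verbatim into the run log.
#'
#' @param threshold inclusive 8-bit segmentation threshold.
#' @param area_gate_um2 punctum area gate (um^2).
#' @param tau_max_s tau inclusion ceiling (s).
#' @param responsive_threshold unloading fraction defining responsiveness
#'   (strict `>`).
#' @param responsive_at_s seconds after onset at which responsiveness is
#'   evaluated.
#' @param background_lag_s seconds after onset of the background reference
#'   frame.
#' @param search_radius registration search radius (px).
#' @param registration_reference reference frame (NULL = last baseline).
#' @param segment_on which branch seeds the ROIs: the registered raw branch
#'   (default; unresponsive puncta are invisible on the subtracted branch)
#'   or the background-subtracted branch.
#' @param segmentation_frame frame whose image seeds the ROIs (default 1,
#'   the first pre-stimulation frame).
#' @param fit_trace trace the exponential is fitted to (see
#'   [analyze_kinetics()]).
#' @param fix_plateau force the fitted plateau to zero.
#' @param egfp_dilation_px dendrite-mask dilation (px).
#' @param restrict_to_egfp analyze only puncta on the eGFP mask.
#' @param marker_threshold,marker_dilation_px marker colocalization settings.
#' @return Class `fm_params`.
#' @export
analysis_params <- function(threshold = 15,
                            area_gate_um2 = c(0.4, 10),
                            tau_max_s = 360,
                            responsive_threshold = 0.05,
                            responsive_at_s = 60,
                            background_lag_s = 180,
                            search_radius = 8L,
                            registration_reference = NULL,
                            segment_on = c("raw", "bgsub"),
                            segmentation_frame = 1L,
                            fit_trace = c("raw", "bgsub"),
                            fix_plateau = FALSE,
                            egfp_dilation_px = 2L,
                            restrict_to_egfp = FALSE,
                            marker_threshold = 15,
                            marker_dilation_px = 1L) {
  p <- as.list(environment())
  p$segment_on <- match.arg(segment_on)
  p$fit_trace <- match.arg(fit_trace)
  stopifnot(p$threshold >= 0, length(p$area_gate_um2) == 2L,
            p$tau_max_s > 0, p$responsive_threshold > 0,
            p$responsive_at_s > 0, p$background_lag_s > 0,
            p$search_radius >= 0, p$segmentation_frame >= 1)
  structure(p, class = "fm_params")
}

#' Run the full destaining analysis on one experiment
#'
#' Accepts either a simulated [fm_experiment][simulate_experiment()] or an
#' `fm_series` (a z-stack or an already-projected series) plus optional
#' eGFP / marker images. The eGFP and marker channels are assumed to be
#' acquired without the stack's stage drift (single acquisitions in scene
#' coordinates); they are translated by the shift applied to frame 1, which
#' maps scene coordinates into the registered reference frame, before
#' colocalization.
#'
#' @param x `fm_experiment` or `fm_series`.
#' @param params an [analysis_params()].
#' @param condition condition label carried into the summary.
#' @param egfp_image,marker_images optional channels (ignored when `x` is an
#'   `fm_experiment`, which carries its own).
#' @param out_dir if non-NULL, results are written there with
#'   [write_results()].
#' @return Class `fm_analysis`: list with `rois`, `kinetics`, `summary`,
#'   `marker_fractions` (named numeric), `egfp_mask`, `shifts`,
#'   `reference_frame`, `background_frame`, `params`, `tables` (the result
#'   data frames as written).
#' @export
run_analysis <- function(x, params = analysis_params(),
                         condition = NA_character_,
                         egfp_image = NULL, marker_images = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(params, "fm_params"))
  if (inherits(x, "fm_experiment")) {
    series <- x$fm_stack
    egfp_image <- x$egfp_image
    marker_images <- x$marker_images
  } else if (inherits(x, "fm_series")) {
    series <- x
  } else {
    stop("`x` must be an fm_experiment or fm_series")
  }

  proj <- sum_project(series)
  eight <- to_8bit(proj)
  reg <- register_series(eight,
                         reference_frame = params$registration_reference,
                         search_radius = params$search_radius)
  bgsub <- subtract_background(reg, lag_s = params$background_lag_s)

  seg_series <- if (params$segment_on == "raw") reg else bgsub
  seg_frame <- seg_series$data[params$segmentation_frame, , ]
  rois <- segment_puncta(seg_frame, series$pixel_size_um,
                         threshold = params$threshold,
                         area_gate_um2 = params$area_gate_um2)

  egfp_mask <- NULL
  if (!is.null(egfp_image)) {
    egfp_mask <- build_egfp_mask(egfp_image,
                                 dilation_px = params$egfp_dilation_px)
    sh <- reg$shifts[1L, ]
    aligned <- translate_frame(egfp_mask$mask * 1, sh[["dy"]],
                               sh[["dx"]]) > 0.5
    rois <- assign_to_mask(rois, aligned)
    names(rois$table)[names(rois$table) == "on_mask"] <- "on_egfp"
  }

  keep <- rois$table$in_gate
  if (params$restrict_to_egfp && !is.null(egfp_mask)) {
    keep <- keep & rois$table$on_egfp
  }
  labels <- rois$table$label[keep]
  if (!length(labels)) stop("no in-gate puncta to analyze")

  kin <- analyze_kinetics(reg, rois, bgsub_series = bgsub, labels = labels,
                          fit_trace = params$fit_trace,
                          unload_threshold = params$responsive_threshold,
                          responsive_at_s = params$responsive_at_s,
                          tau_max_s = params$tau_max_s,
                          fix_plateau = params$fix_plateau)
  summ <- summarize_field(kin, condition = condition)

  marker_fractions <- numeric(0)
  if (length(marker_images)) {
    sh <- reg$shifts[1L, ]
    for (mk in names(marker_images)) {
      mi <- translate_frame(marker_images[[mk]], sh[["dy"]], sh[["dx"]])
      mpf <- marker_positive_fraction(
        rois, mi, marker_threshold = params$marker_threshold,
        dilation_px = params$marker_dilation_px)
      marker_fractions[[mk]] <- mpf$fraction
      rois$table[[paste0("marker_", mk)]] <- mpf$flags$marker_positive
    }
  }

  tables <- list(
    puncta = rois$table,
    kinetics = kin$results,
    mean_curve = summ$mean_curve,
    field_summary = data.frame(
      condition = summ$condition,
      n_puncta_total = summ$n_puncta_total,
      n_responsive = summ$n_responsive,
      n_unresponsive = summ$n_unresponsive,
      pct_responsive = summ$pct_responsive,
      tau_mean_s = summ$tau_mean_s,
      tau_sem_s = summ$tau_sem_s,
      tau_n = summ$tau_n,
      n_tau_excluded = summ$n_tau_excluded))

  if (!is.null(out_dir)) {
    write_results(tables, out_dir,
                  run_info = list(params = unclass(params),
                                  condition = condition,
                                  reference_frame = reg$reference_frame,
                                  background_frame = bgsub$background_frame,
                                  shifts = reg$shifts))
  }

  structure(list(rois = rois, kinetics = kin, summary = summ,
                 marker_fractions = marker_fractions,
                 egfp_mask = egfp_mask,
                 shifts = reg$shifts,
                 reference_frame = reg$reference_frame,
                 background_frame = bgsub$background_frame,
                 params = params, tables = tables),
            class = "fm_analysis")
}

#' @export
print.fm_analysis <- function(x, ...) {
  cat("<fm_analysis>\n")
  print(x$summary)
  if (length(x$marker_fractions)) {
    cat("  marker-positive fractions:",
        paste(sprintf("%s = %.2f", names(x$marker_fractions),
                      x$marker_fractions), collapse = ", "), "\n")
  }
  invisible(x)
}
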