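# Unloading kinetics: trace extraction, normalization, responsiveness
# classification, single-exponential fitting, tau exclusion, field summary.

#' Extract per-punctum intensity traces
#'
#' The trace of a punctum is the arithmetic mean of its ROI pixels in each
#' frame.
#'
#' @param series an `fm_series` with 3-D data (`T x Y x X`).
#' @param rois an `fm_rois` whose label image matches the field shape.
#' @param labels which labels to extract (default: all).
#' @return Numeric matrix `T x n_puncta`; column names are the labels.
#' @export
extract_traces <- function(series, rois, labels = NULL) {
  stopifnot(inherits(series, "fm_series"), length(dim(series$data)) == 3L,
            inherits(rois, "fm_rois"))
  d <- dim(series$data)
  stopifnot(identical(d[2:3], dim(rois$label_image)))
  labels <- labels %||% rois$table$label
  m <- matrix(series$data, nrow = d[1])   # T x (Y*X), column-major in (Y,X)
  out <- matrix(NA_real_, d[1], length(labels),
                dimnames = list(NULL, labels))
  for (j in seq_along(labels)) {
    cols <- which(rois$label_image == labels[j])
    if (!length(cols)) stop("label ", labels[j], " not present in ROI image")
    out[, j] <- rowMeans(m[, cols, drop = FALSE])
  }
  out
}

#' Normalize a trace to the last pre-stimulation frame
#'
#' Pointwise division by the trace value at `stim_onset_frame - 1`, so the
#' normalized trace is exactly 1 there. A zero or negative reference value
#' cannot be divided through: the punctum is excluded by returning an all-NA
#' trace carrying a `reason` attribute (`"nonpositive_reference"`).
#'
#' @param trace numeric vector.
#' @param stim_onset_frame 1-based index of the first stimulation frame.
#' @return Normalized trace, or all-NA with attribute `reason`.
#' @export
normalize_trace <- function(trace, stim_onset_frame) {
  stopifnot(is.numeric(trace), stim_onset_frame >= 2,
            stim_onset_frame <= length(trace))
  ref <- trace[stim_onset_frame - 1L]
  if (!is.finite(ref) || ref <= 0) {
    out <- rep(NA_real_, length(trace))
    attr(out, "reason") <- "nonpositive_reference"
    return(out)
  }
  trace / ref
}

#' Classify a punctum as responsive
#'
#' A punctum is responsive iff it unloads strictly more than
#' `unload_threshold` (default 5%) of its normalized fluorescence by
#' `at_s` seconds (default 60 s) after stimulation onset, i.e. iff the
#' normalized value at the frame nearest that time is `< 1 - threshold`
#' (strict: exactly 5% unloading is unresponsive). Classification is defined
#' on traces from the registered, non-background-subtracted stack.
#'
#' @param norm_trace normalized trace (see [normalize_trace()]).
#' @param times_s frame times in seconds.
#' @param stim_onset_frame 1-based first stimulation frame.
#' @param unload_threshold unloading fraction defining responsiveness.
#' @param at_s time after onset at which unloading is evaluated.
#' @return List: `responsive` (logical, NA if the trace is NA),
#'   `unloading_frac` (1 - normalized value), `frame_index` (frame used).
#' @export
classify_responsive <- function(norm_trace, times_s, stim_onset_frame,
                                unload_threshold = 0.05, at_s = 60) {
  stopifnot(length(norm_trace) == length(times_s),
            stim_onset_frame >= 2, stim_onset_frame <= length(times_s))
  target <- times_s[stim_onset_frame] + at_s
  idx <- nearest_frame_index(times_s, target)
  v <- norm_trace[idx]
  frac <- 1 - v
  # strict: exactly (1 - threshold) is unresponsive; compared on the
  # normalized scale so the boundary is exact
  list(responsive = if (is.na(v)) NA else unname(v < 1 - unload_threshold),
       unloading_frac = unname(frac),
       frame_index = idx)
}

#' Fit a single-exponential decay to an unloading trace
#'
#' Least-squares fit of `f(t) = C + A * exp(-(t - t_onset) / tau)` to the
#' frames from stimulation onset to the end of the series, with constraints
#' `A >= 0`, `C >= 0`, `tau > 0` (Levenberg-Marquardt with box bounds).
#' Starting values: `A0 = f(t_onset) - f(t_end)`, `C0 = f(t_end)`,
#' `tau0 = 60 s`. The plateau `C` is free because FM destaining rarely
#' reaches zero; `fix_plateau = TRUE` forces `C = 0`.
#'
#' @param norm_trace normalized trace to fit.
#' @param times_s frame times in seconds.
#' @param stim_onset_frame 1-based first stimulation frame; at least 4 frames
#'   from onset onwards are required.
#' @param tau_init_s starting value for tau.
#' @param fix_plateau force the plateau to zero.
#' @return List: `tau_s`, `amplitude`, `plateau`, `rss`, `converged`,
#'   `reason` (NA on success). On failure `tau_s` is NA.
#' @export
fit_single_exponential <- function(norm_trace, times_s, stim_onset_frame,
                                   tau_init_s = 60, fix_plateau = FALSE) {
  stopifnot(length(norm_trace) == length(times_s), stim_onset_frame >= 1)
  idx <- stim_onset_frame:length(norm_trace)
  if (length(idx) < 4L) stop("need at least 4 frames from stimulation onset")
  y <- norm_trace[idx]
  tt <- times_s[idx]
  failed <- function(reason) {
    list(tau_s = NA_real_, amplitude = NA_real_, plateau = NA_real_,
         rss = NA_real_, converged = FALSE, reason = reason)
  }
  if (anyNA(y)) return(failed("missing_values"))
  t0 <- tt[1]
  a0 <- max(y[1] - y[length(y)], 1e-6)
  c0 <- max(y[length(y)], 0)
  # Levenberg-Marquardt with box constraints, called directly: the nls-model
  # wrapper cannot represent zero-residual (noiseless) solutions
  resid_fn <- if (fix_plateau) {
    function(p) y - p[["A"]] * exp(-(tt - t0) / p[["tau"]])
  } else {
    function(p) y - (p[["C"]] + p[["A"]] * exp(-(tt - t0) / p[["tau"]]))
  }
  par0 <- if (fix_plateau) {
    c(A = a0, tau = tau_init_s)
  } else {
    c(A = a0, C = c0, tau = tau_init_s)
  }
  lower <- setNames(c(rep(0, length(par0) - 1L), 1e-6), names(par0))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  if (!(fit$info %in% 1:4)) return(failed(fit$message))
  p <- fit$par
  tau <- unname(p[["tau"]])
  amp <- unname(p[["A"]])
  plateau <- if (fix_plateau) 0 else unname(p[["C"]])
  # a decay that explains nothing (flat trace) has no meaningful tau
  if (amp < 1e-6 || tau > 1e3 * (tt[length(tt)] - t0)) {
    return(failed("no_decay"))
  }
  list(tau_s = tau, amplitude = amp, plateau = plateau,
       rss = fit$deviance, converged = TRUE, reason = NA_character_)
}

#' Apply the tau exclusion rule
#'
#' Fitted puncta with decay constants above `tau_max_s` (default 360 s) are
#' flagged as excluded and assumed non-releasing; they are reported, never
#' silently dropped. The rule is monotone: a stricter ceiling includes a
#' subset of the puncta a looser one does.
#'
#' @param results data frame with a `tau_s` column (see [analyze_kinetics()]).
#' @param tau_max_s inclusion ceiling in seconds.
#' @return `results` with an `included` logical column (re)computed:
#'   `included <- !is.na(tau_s) & tau_s <= tau_max_s`.
#' @export
apply_tau_exclusion <- function(results, tau_max_s = 360) {
  stopifnot(is.data.frame(results), "tau_s" %in% names(results),
            tau_max_s > 0)
  results$included <- !is.na(results$tau_s) & results$tau_s <= tau_max_s
  results
}

#' Per-punctum unloading kinetics
#'
#' Runs the kinetics chain for every requested punctum: trace extraction
#' from the raw (registered) and background-subtracted series, normalization
#' to the last pre-stimulation frame, responsiveness classification on the
#' raw normalized trace, single-exponential fitting of responsive puncta,
#' and tau exclusion. Fitting defaults to the raw normalized trace, where
#' the free plateau absorbs background and the non-releasable residual; see
#' the package vignette for why fitting reference-subtracted traces with a
#' non-negative plateau is biased. `fit_trace = "bgsub"` selects the
#' background-subtracted trace instead.
#'
#' @param raw_series registered, non-background-subtracted `fm_series`.
#' @param rois an `fm_rois`.
#' @param bgsub_series background-subtracted companion series (optional
#'   unless `fit_trace = "bgsub"`).
#' @param labels puncta to analyze (default: in-gate puncta).
#' @param fit_trace which trace the exponential is fitted to.
#' @param unload_threshold,responsive_at_s see [classify_responsive()].
#' @param tau_max_s see [apply_tau_exclusion()].
#' @param fix_plateau see [fit_single_exponential()].
#' @return Class `fm_kinetics`: list with `results` (one row per punctum:
#'   `punctum_id`, `unloading_frac_60s`, `responsive`, `tau_s`, `amplitude`,
#'   `plateau`, `rss`, `converged`, `included`, `reason`), `traces` (list of
#'   matrices: `raw`, `bgsub`, `norm_raw`, `norm_fit`), `times_s`,
#'   `stim_onset_frame`.
#' @export
analyze_kinetics <- function(raw_series, rois, bgsub_series = NULL,
                             labels = NULL,
                             fit_trace = c("raw", "bgsub"),
                             unload_threshold = 0.05, responsive_at_s = 60,
                             tau_max_s = 360, fix_plateau = FALSE) {
  fit_trace <- match.arg(fit_trace)
  if (fit_trace == "bgsub" && is.null(bgsub_series)) {
    stop("fit_trace = \"bgsub\" requires `bgsub_series`")
  }
  labels <- labels %||% rois$table$label[rois$table$in_gate]
  onset <- raw_series$stim_onset_frame
  times <- frame_times(raw_series)
  raw <- extract_traces(raw_series, rois, labels)
  bgs <- if (!is.null(bgsub_series)) {
    extract_traces(bgsub_series, rois, labels)
  }
  norm_raw <- apply(raw, 2, normalize_trace, stim_onset_frame = onset)
  norm_fit <- if (fit_trace == "raw") {
    norm_raw
  } else {
    apply(bgs, 2, normalize_trace, stim_onset_frame = onset)
  }
  n <- length(labels)
  res <- data.frame(punctum_id = labels,
                    unloading_frac_60s = NA_real_, responsive = NA,
                    tau_s = NA_real_, amplitude = NA_real_,
                    plateau = NA_real_, rss = NA_real_,
                    converged = FALSE, included = FALSE,
                    reason = NA_character_)
  for (j in seq_len(n)) {
    if (all(is.na(norm_raw[, j]))) {
      res$reason[j] <- "nonpositive_reference"
      next
    }
    cls <- classify_responsive(norm_raw[, j], times, onset,
                               unload_threshold, responsive_at_s)
    res$unloading_frac_60s[j] <- cls$unloading_frac
    res$responsive[j] <- cls$responsive
    if (!isTRUE(cls$responsive)) next      # only unloaded puncta are fitted
    if (all(is.na(norm_fit[, j]))) {
      res$reason[j] <- "nonpositive_reference_fit"
      next
    }
    fit <- fit_single_exponential(norm_fit[, j], times, onset,
                                  fix_plateau = fix_plateau)
    res$tau_s[j] <- fit$tau_s
    res$amplitude[j] <- fit$amplitude
    res$plateau[j] <- fit$plateau
    res$rss[j] <- fit$rss
    res$converged[j] <- fit$converged
    res$reason[j] <- fit$reason
  }
  res <- apply_tau_exclusion(res, tau_max_s)
  structure(list(results = res,
                 traces = list(raw = raw, bgsub = bgs,
                               norm_raw = norm_raw, norm_fit = norm_fit),
                 times_s = times, stim_onset_frame = onset),
            class = "fm_kinetics")
}

#' Summarize a neuron field
#'
#' Aggregates per-punctum kinetics into the per-field quantities reported in
#' destaining experiments: responsive/unresponsive counts, percent
#' responsive, the mean +/- s.e.m. of included decay constants, and the mean
#' normalized unloading curve (per-timepoint mean +/- s.e.m. across
#' responsive puncta, raw normalized traces).
#'
#' @param kinetics an `fm_kinetics`.
#' @param condition optional condition label carried into the summary.
#' @return Class `fm_field_summary`: list with `condition`, `n_responsive`,
#'   `n_unresponsive`, `pct_responsive`, `n_puncta_total`, `n_tau_excluded`,
#'   `tau_mean_s`, `tau_sem_s`, `tau_n`, `mean_curve` (data frame `time_s`,
#'   `mean`, `sem`, `n`).
#' @export
summarize_field <- function(kinetics, condition = NA_character_) {
  stopifnot(inherits(kinetics, "fm_kinetics"))
  res <- kinetics$results
  if (!nrow(res)) stop("no puncta to summarize")
  n_resp <- sum(res$responsive, na.rm = TRUE)
  n_unresp <- sum(!res$responsive, na.rm = TRUE)
  taus <- res$tau_s[res$included]
  n_exc <- sum(res$converged & !res$included)
  curves <- kinetics$traces$norm_raw[, which(res$responsive %in% TRUE),
                                     drop = FALSE]
  mean_curve <- data.frame(
    time_s = kinetics$times_s,
    mean = if (ncol(curves)) rowMeans(curves) else NA_real_,
    sem = if (ncol(curves) > 1) {
      apply(curves, 1, sd) / sqrt(ncol(curves))
    } else {
      NA_real_
    },
    n = ncol(curves))
  structure(list(condition = condition,
                 n_responsive = n_resp,
                 n_unresponsive = n_unresp,
                 pct_responsive = 100 * n_resp / (n_resp + n_unresp),
                 n_puncta_total = nrow(res),
                 n_tau_excluded = n_exc,
                 tau_mean_s = if (length(taus)) mean(taus) else NA_real_,
                 tau_sem_s = if (length(taus) > 1) {
                   sd(taus) / sqrt(length(taus))
                 } else {
                   NA_real_
                 },
                 tau_n = length(taus),
                 mean_curve = mean_curve),
            class = "fm_field_summary")
}

#' @export
print.fm_field_summary <- function(x, ...) {
  cat("<fm_field_summary>",
      if (!is.na(x$condition)) paste0("[", x$condition, "]"), "\n")
  cat(sprintf("  puncta: %d total, %d responsive / %d unresponsive (%.1f%%)\n",
              x$n_puncta_total, x$n_responsive, x$n_unresponsive,
              x$pct_responsive))
  if (!is.na(x$tau_mean_s)) {
    cat(sprintf("  tau: %.1f +/- %.1f s (mean +/- s.e.m., n = %d; %d excluded)\n",
                x$tau_mean_s, x$tau_sem_s, x$tau_n, x$n_tau_excluded))
  }
  invisible(x)
}

#' Plot the mean unloading curve of a field summary
#'
#' @param x an `fm_field_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fm_field_summary <- function(x, ...) {
  mc <- x$mean_curve
  graphics::plot(mc$time_s, mc$mean, type = "b", pch = 16,
                 xlab = "time (s)", ylab = "normalized fluorescence",
                 ylim = range(c(mc$mean - mc$sem, mc$mean + mc$sem, 1),
                              na.rm = TRUE), ...)
  graphics::arrows(mc$time_s, mc$mean - mc$sem, mc$time_s, mc$mean + mc$sem,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}
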