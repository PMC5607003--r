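# Closed-form quantifications and cross-condition comparisons.

#' Percent cell viability from Hoechst / Sytox counts
#'
#' `[(Hoechst - Sytox+) / Hoechst] x 100`, with Hoechst counting all nuclei
#' and Sytox+ the dead cells.
#'
#' @param n_hoechst total nuclei (> 0).
#' @param n_sytox Sytox-positive (dead) cells, `0 <= n_sytox <= n_hoechst`.
#' @return Percent viability.
#' @export
viability_percent <- function(n_hoechst, n_sytox) {
  stopifnot(is.numeric(n_hoechst), is.numeric(n_sytox),
            all(n_hoechst > 0), all(n_sytox >= 0), all(n_sytox <= n_hoechst))
  (n_hoechst - n_sytox) / n_hoechst * 100
}

#' Dendritic spine density per 10 um of dendrite
#'
#' `(# spines / dendrite length) x 10`. Invariant to scaling spines and
#' length together.
#'
#' @param n_spines spine count (>= 0).
#' @param dendrite_length_um total dendritic length in micrometres (> 0).
#' @return Spines per 10 um.
#' @export
spine_density_per_10um <- function(n_spines, dendrite_length_um) {
  stopifnot(is.numeric(n_spines), all(n_spines >= 0),
            is.numeric(dendrite_length_um), all(dendrite_length_um > 0))
  n_spines / dendrite_length_um * 10
}

#' Compare decay constants between two conditions
#'
#' Unpaired two-tailed Welch t-test on per-punctum decay constants, plus the
#' group means +/- s.e.m. Identical groups give `t = 0`, `p = 1` even when
#' both are constant.
#'
#' @param group_a_taus,group_b_taus numeric vectors (each `n >= 2`).
#' @return Class `fm_tau_test`: list with `t`, `df`, `p_value`, and per-group
#'   `mean`, `sem`, `n`.
#' @export
compare_tau <- function(group_a_taus, group_b_taus) {
  a <- group_a_taus[is.finite(group_a_taus)]
  b <- group_b_taus[is.finite(group_b_taus)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 finite values")
  }
  ht <- welch_row(a, b)
  structure(list(t = ht$t, df = ht$df, p_value = ht$p,
                 mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)),
                 n_a = length(a),
                 mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)),
                 n_b = length(b)),
            class = "fm_tau_test")
}

#' @export
print.fm_tau_test <- function(x, ...) {
  cat(sprintf(
    "<fm_tau_test> %.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d)\n",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("  Welch t = %.3f, df = %.1f, two-tailed p = %.4g\n",
              x$t, x$df, x$p_value))
  invisible(x)
}

# Welch test of two samples with degenerate cases resolved deterministically:
# equal means -> t = 0, p = 1; zero variance in both with unequal means ->
# p = 0.
welch_row <- function(a, b) {
  if (isTRUE(all.equal(mean(a), mean(b))) &&
      (sd(a) == 0 && sd(b) == 0)) {
    return(list(t = 0, df = NA_real_, p = 1))
  }
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(t = Inf, df = NA_real_, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Per-timepoint comparison of unloading curves
#'
#' Compares two sets of per-punctum normalized unloading curves timepoint by
#' timepoint with Welch t-tests, Bonferroni-adjusted across timepoints. This
#' deliberately replaces an omnibus repeated-measures ANOVA: the goal is a
#' transparent per-timepoint verification, and the output says so.
#'
#' @param curves_a,curves_b numeric matrices `T x n_puncta` on matching time
#'   axes (columns are puncta).
#' @param times_s optional time axis, length `T`.
#' @return Data frame with one row per timepoint: `time_s`, `mean_a`,
#'   `sem_a`, `mean_b`, `sem_b`, `t`, `df`, `p`, `p_adj`. Attribute `note`
#'   records the testing scheme.
#' @export
compare_curves <- function(curves_a, curves_b, times_s = NULL) {
  stopifnot(is.matrix(curves_a), is.matrix(curves_b),
            nrow(curves_a) == nrow(curves_b),
            ncol(curves_a) >= 2L, ncol(curves_b) >= 2L)
  nt <- nrow(curves_a)
  times_s <- times_s %||% seq_len(nt)
  stopifnot(length(times_s) == nt)
  out <- data.frame(time_s = times_s, mean_a = NA_real_, sem_a = NA_real_,
                    mean_b = NA_real_, sem_b = NA_real_, t = NA_real_,
                    df = NA_real_, p = NA_real_)
  for (i in seq_len(nt)) {
    a <- curves_a[i, ]
    b <- curves_b[i, ]
    ht <- welch_row(a, b)
    out$mean_a[i] <- mean(a)
    out$sem_a[i] <- sd(a) / sqrt(length(a))
    out$mean_b[i] <- mean(b)
    out$sem_b[i] <- sd(b) / sqrt(length(b))
    out$t[i] <- ht$t
    out$df[i] <- ht$df
    out$p[i] <- ht$p
  }
  out$p_adj <- p.adjust(out$p, method = "bonferroni")
  attr(out, "note") <- paste(
    "Per-timepoint Welch tests with Bonferroni adjustment across",
    "timepoints; NOT a repeated-measures two-way ANOVA.")
  out
}
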