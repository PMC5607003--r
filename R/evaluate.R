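# Validation of pipeline output against simulator ground truth.

#' Match detected puncta to ground-truth centres
#'
#' Ground-truth centres are mapped into registered coordinates by adding
#' `drift_ref_yx` (the applied drift of the registration reference frame;
#' `(0, 0)` for drift-free data) and matched one-to-one to in-gate detected
#' centroids, closest pairs first, within `match_radius_px`.
#'
#' @param analysis an `fm_analysis` or `fm_rois`.
#' @param truth simulator truth table (or `fm_experiment`).
#' @param drift_ref_yx length-2 `(dy, dx)` of the reference frame.
#' @param match_radius_px maximum centre-to-centroid distance.
#' @return List: `precision`, `recall`, `n_matched`, `matches` (data frame
#'   `truth_id`, `label`, `dist_px`).
#' @export
evaluate_segmentation <- function(analysis, truth, drift_ref_yx = c(0, 0),
                                  match_radius_px = 2) {
  rois <- if (inherits(analysis, "fm_analysis")) analysis$rois else analysis
  stopifnot(inherits(rois, "fm_rois"))
  if (inherits(truth, "fm_experiment")) truth <- truth$truth
  det <- rois$table[rois$table$in_gate, , drop = FALSE]
  ty <- truth$y_px + drift_ref_yx[1]
  tx <- truth$x_px + drift_ref_yx[2]
  matches <- data.frame(truth_id = integer(0), label = integer(0),
                        dist_px = numeric(0))
  if (nrow(det) && nrow(truth)) {
    d <- sqrt(outer(det$centroid_y, ty, "-")^2 +
              outer(det$centroid_x, tx, "-")^2)
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > match_radius_px) break
      i <- ((m - 1) %% nrow(d)) + 1
      j <- ((m - 1) %/% nrow(d)) + 1
      matches <- rbind(matches,
                       data.frame(truth_id = truth$id[j],
                                  label = det$label[i],
                                  dist_px = d[m]))
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  list(precision = if (nrow(det)) nrow(matches) / nrow(det) else NA_real_,
       recall = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_,
       n_matched = nrow(matches),
       matches = matches)
}

#' Score kinetics output against ground truth
#'
#' Joins matched puncta to the truth table and reports the
#' responsive/unresponsive classification accuracy and the relative error of
#' fitted decay constants for truth-responsive, successfully fitted puncta.
#'
#' @param analysis an `fm_analysis`.
#' @param truth simulator truth table (or `fm_experiment`).
#' @param matches the `matches` frame from [evaluate_segmentation()].
#' @return List: `classification_accuracy`, `n_classified`,
#'   `median_rel_tau_error`, `tau_table` (data frame `truth_id`, `label`,
#'   `tau_true_s`, `tau_s`, `rel_error`).
#' @export
evaluate_kinetics <- function(analysis, truth, matches) {
  stopifnot(inherits(analysis, "fm_analysis"))
  if (inherits(truth, "fm_experiment")) truth <- truth$truth
  res <- analysis$kinetics$results
  j <- merge(matches, truth, by.x = "truth_id", by.y = "id")
  # truth's flag becomes responsive.x, the pipeline's responsive.y
  j <- merge(j, res, by.x = "label", by.y = "punctum_id")
  cls <- j[!is.na(j$responsive.y), , drop = FALSE]
  acc <- if (nrow(cls)) {
    mean(cls$responsive.x == cls$responsive.y)
  } else {
    NA_real_
  }
  tt <- j[j$responsive.x & !is.na(j$tau_s), , drop = FALSE]
  rel <- abs(tt$tau_s - tt$tau_true_s) / tt$tau_true_s
  list(classification_accuracy = acc,
       n_classified = nrow(cls),
       median_rel_tau_error = if (length(rel)) median(rel) else NA_real_,
       tau_table = data.frame(truth_id = tt$truth_id, label = tt$label,
                              tau_true_s = tt$tau_true_s, tau_s = tt$tau_s,
                              rel_error = rel))
}
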