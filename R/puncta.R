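# Punctum segmentation, the area gate, the eGFP dendrite mask, and
# marker colocalization.

#' 8-connected component labelling
#'
#' Labels connected sets of `TRUE` pixels using 8-connectivity (edge and
#' corner neighbours), the convention under which two diagonally touching
#' pixels belong to one punctum. Labels are positive integers numbered in
#' raster (column-major) order of first appearance; background is 0.
#'
#' @param fg logical matrix of foreground pixels.
#' @return Integer matrix of the same shape.
#' @export
label_components <- function(fg) {
  stopifnot(is.matrix(fg), is.logical(fg))
  ny <- nrow(fg)
  nx <- ncol(fg)
  lab <- matrix(0L, ny, nx)
  if (!any(fg)) return(lab)
  parent <- integer(0)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) {     # path compression
      j <- parent[i]
      parent[i] <<- r
      i <- j
    }
    r
  }
  link <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  nlab <- 0L
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!fg[y, x]) next
      nb <- integer(0)
      if (x > 1L) {
        if (y > 1L && lab[y - 1L, x - 1L]) nb <- c(nb, lab[y - 1L, x - 1L])
        if (lab[y, x - 1L])                nb <- c(nb, lab[y, x - 1L])
        if (y < ny && lab[y + 1L, x - 1L]) nb <- c(nb, lab[y + 1L, x - 1L])
      }
      if (y > 1L && lab[y - 1L, x])        nb <- c(nb, lab[y - 1L, x])
      if (!length(nb)) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        lab[y, x] <- nlab
      } else {
        lab[y, x] <- nb[1L]
        for (o in nb[-1L]) link(nb[1L], o)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  # renumber roots compactly in raster order of first appearance
  remap <- integer(nlab)
  nxt <- 0L
  idx <- which(lab > 0L)
  vals <- roots[lab[idx]]
  for (k in seq_along(idx)) {
    r <- vals[k]
    if (remap[r] == 0L) {
      nxt <- nxt + 1L
      remap[r] <- nxt
    }
  }
  lab[idx] <- remap[vals]
  lab
}

#' Segment FM puncta by intensity threshold and area gate
#'
#' Pixels at or above `threshold` (inclusive, matching the pipeline's
#' threshold of 15 on 8-bit images) form the foreground; 8-connected
#' components become candidate puncta. Components whose area falls outside
#' `area_gate_um2` (default 0.4-10 um^2) are flagged out-of-gate and are
#' excluded from downstream kinetics.
#'
#' @param frame 2-D numeric matrix (normally an 8-bit frame).
#' @param pixel_size_um pixel edge length in micrometres.
#' @param threshold inclusive foreground threshold.
#' @param area_gate_um2 length-2 numeric, inclusive area gate in um^2.
#' @return An object of class `fm_rois`: a list with `table` (data frame:
#'   `label`, `centroid_y`, `centroid_x`, `n_pixels`, `area_um2`, `in_gate`),
#'   `label_image`, `pixel_size_um`, `threshold`, `area_gate_um2`. The table
#'   may have zero rows.
#' @export
segment_puncta <- function(frame, pixel_size_um, threshold = 15,
                           area_gate_um2 = c(0.4, 10)) {
  stopifnot(is.matrix(frame), is.numeric(frame),
            length(area_gate_um2) == 2L, area_gate_um2[1] <= area_gate_um2[2])
  lab <- label_components(frame >= threshold)
  n <- max(lab)
  if (n == 0L) {
    tab <- data.frame(label = integer(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), n_pixels = integer(0),
                      area_um2 = numeric(0), in_gate = logical(0))
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    yy <- ((idx - 1L) %% nrow(frame)) + 1L
    xx <- ((idx - 1L) %/% nrow(frame)) + 1L
    npx <- tabulate(l, nbins = n)
    cy <- rowsum(as.numeric(yy), l)[, 1] / npx
    cx <- rowsum(as.numeric(xx), l)[, 1] / npx
    area <- area_px_to_um2(npx, pixel_size_um)
    tab <- data.frame(label = seq_len(n), centroid_y = cy, centroid_x = cx,
                      n_pixels = npx, area_um2 = area,
                      in_gate = area >= area_gate_um2[1] &
                                area <= area_gate_um2[2])
    rownames(tab) <- NULL
  }
  structure(list(table = tab, label_image = lab,
                 pixel_size_um = pixel_size_um, threshold = threshold,
                 area_gate_um2 = area_gate_um2),
            class = "fm_rois")
}

#' @export
print.fm_rois <- function(x, ...) {
  cat(sprintf("<fm_rois> %d components, %d in the %.1f-%.1f um^2 gate\n",
              nrow(x$table), sum(x$table$in_gate),
              x$area_gate_um2[1], x$area_gate_um2[2]))
  invisible(x)
}

#' Build the eGFP dendrite mask
#'
#' Thresholds the eGFP image with Otsu's bimodal-split method and dilates the
#' result by `dilation_px` (disc structuring element) so that the outline
#' encloses labelled regions including spines. A constant image yields an
#' empty mask with a warning.
#'
#' @param egfp_image 2-D numeric matrix.
#' @param dilation_px dilation radius in pixels (0 disables).
#' @return Class `fm_egfp_mask`: list with `mask` (logical matrix),
#'   `threshold_used` (on the original intensity scale), `dilation_px`.
#' @export
build_egfp_mask <- function(egfp_image, dilation_px = 2L) {
  stopifnot(is.matrix(egfp_image), is.numeric(egfp_image), dilation_px >= 0)
  lo <- min(egfp_image)
  hi <- max(egfp_image)
  if (hi == lo) {
    warning("constant eGFP image; returning an empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(egfp_image),
                                        ncol(egfp_image)),
                          threshold_used = NA_real_,
                          dilation_px = as.integer(dilation_px)),
                     class = "fm_egfp_mask"))
  }
  v <- (egfp_image - lo) / (hi - lo)
  thr <- EBImage::otsu(EBImage::Image(v), range = c(0, 1))
  mask <- v > thr
  if (dilation_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L,
                                shape = "disc")
    mask <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  }
  mask <- matrix(as.logical(mask), nrow(egfp_image), ncol(egfp_image))
  structure(list(mask = mask, threshold_used = lo + thr * (hi - lo),
                 dilation_px = as.integer(dilation_px)),
            class = "fm_egfp_mask")
}

#' Assign puncta to a mask by centroid membership
#'
#' A punctum belongs to the mask iff its centroid pixel (nearest-pixel
#' rounding) lies inside the mask — deterministic and unambiguous even for
#' thin dendrite masks.
#'
#' @param rois an `fm_rois`.
#' @param mask logical matrix (same field shape) or an `fm_egfp_mask`.
#' @return `rois` with a logical `on_mask` column added to its table.
#' @export
assign_to_mask <- function(rois, mask) {
  stopifnot(inherits(rois, "fm_rois"))
  if (inherits(mask, "fm_egfp_mask")) mask <- mask$mask
  stopifnot(is.matrix(mask), is.logical(mask),
            identical(dim(mask), dim(rois$label_image)))
  tab <- rois$table
  if (nrow(tab)) {
    py <- pmin(pmax(round(tab$centroid_y), 1L), nrow(mask))
    px <- pmin(pmax(round(tab$centroid_x), 1L), ncol(mask))
    tab$on_mask <- mask[cbind(py, px)]
  } else {
    tab$on_mask <- logical(0)
  }
  rois$table <- tab
  rois
}

#' Fraction of FM puncta positive for an immunomarker
#'
#' Marker foci are detected by running [segment_puncta()] on the marker
#' channel (converted to 8-bit, with its own threshold and gate). An FM
#' punctum is marker-positive iff any marker-focus centroid falls within the
#' punctum's pixels dilated by `dilation_px`. The fraction is taken over
#' in-gate FM puncta.
#'
#' @param rois FM puncta (`fm_rois`).
#' @param marker_image 2-D numeric matrix aligned to the FM field.
#' @param marker_threshold threshold applied to the 8-bit marker image.
#' @param dilation_px tolerance dilation of FM punctum pixels.
#' @param marker_area_gate_um2 area gate for marker foci.
#' @return List: `fraction` (NA with a warning if there are no in-gate
#'   puncta), `flags` (data frame `label`, `marker_positive`),
#'   `n_marker_foci`.
#' @export
marker_positive_fraction <- function(rois, marker_image,
                                     marker_threshold = 15,
                                     dilation_px = 1L,
                                     marker_area_gate_um2 = c(0.4, 10)) {
  stopifnot(inherits(rois, "fm_rois"),
            identical(dim(marker_image), dim(rois$label_image)))
  m8 <- to_8bit(marker_image)
  mrois <- segment_puncta(m8, rois$pixel_size_um, marker_threshold,
                          marker_area_gate_um2)
  foci <- mrois$table[mrois$table$in_gate, , drop = FALSE]
  lab <- rois$label_image
  if (dilation_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L,
                                shape = "box")
    lab <- matrix(as.integer(EBImage::dilate(EBImage::Image(lab), brush)),
                  nrow(lab), ncol(lab))
  }
  pos_labels <- integer(0)
  if (nrow(foci)) {
    py <- pmin(pmax(round(foci$centroid_y), 1L), nrow(lab))
    px <- pmin(pmax(round(foci$centroid_x), 1L), ncol(lab))
    pos_labels <- unique(lab[cbind(py, px)])
    pos_labels <- pos_labels[pos_labels > 0L]
  }
  tab <- rois$table
  flags <- data.frame(label = tab$label,
                      marker_positive = tab$label %in% pos_labels)
  n_gate <- sum(tab$in_gate)
  fraction <- if (n_gate == 0L) {
    warning("no in-gate FM puncta; marker fraction is undefined")
    NA_real_
  } else {
    sum(flags$marker_positive & tab$in_gate) / n_gate
  }
  list(fraction = fraction, flags = flags,
       n_marker_foci = nrow(foci))
}
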