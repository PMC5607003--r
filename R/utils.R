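# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Index of the frame nearest to a target time
#'
#' Ties (a target exactly between two frames) resolve to the later frame.
#'
#' @param times_s numeric vector of frame times in seconds.
#' @param target_s target time in seconds.
#' @return 1-based frame index.
#' @export
nearest_frame_index <- function(times_s, target_s) {
  stopifnot(is.numeric(times_s), length(times_s) >= 1, is.finite(target_s))
  d <- abs(times_s - target_s)
  idx <- which(d == min(d))
  idx[length(idx)]
}

#' Convert a pixel count to an area in square micrometres
#'
#' The single place where pixel areas become physical areas:
#' `area_um2 = n_pixels * pixel_size_um^2`.
#'
#' @param n_pixels integer pixel count(s).
#' @param pixel_size_um pixel edge length in micrometres.
#' @return area(s) in um^2.
#' @export
area_px_to_um2 <- function(n_pixels, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  n_pixels * pixel_size_um^2
}

#' Convert a length in micrometres to pixels
#'
#' Companion of [area_px_to_um2()]; all um/px conversions go through this pair.
#'
#' @param um length in micrometres.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return length in pixels (not rounded).
#' @export
um_to_px <- function(um, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  um / pixel_size_um
}

# Integer translation with zero fill: out[y, x] = m[y - dy, x - dx].
translate_frame <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m)
  nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy   # source rows
  xs <- seq_len(nx) - dx   # source cols
  oky <- ys >= 1 & ys <= ny
  okx <- xs >= 1 & xs <= nx
  if (any(oky) && any(okx)) {
    out[which(oky), which(okx)] <- m[ys[oky], xs[okx], drop = FALSE]
  }
  out
}
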