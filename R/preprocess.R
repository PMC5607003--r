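# Image preparation: sum projection, 8-bit conversion, rigid translation
# registration, and reference-frame background subtraction.

#' Sum-project a z-stack series
#'
#' Each output pixel is the sum over the Z axis. Performed in double
#' precision, so no overflow can occur before the 8-bit conversion.
#'
#' @param x an `fm_series` with a Z axis, or a `T x Z x Y x X` array.
#' @return The same type with Z summed out (`T x Y x X`).
#' @export
sum_project <- function(x) {
  a <- if (inherits(x, "fm_series")) x$data else x
  stopifnot(is.array(a))
  if (length(dim(a)) == 3L) {
    # already projected; identity keeps the pipeline composable
    return(x)
  }
  stopifnot(length(dim(a)) == 4L)
  b <- aperm(a, c(2L, 1L, 3L, 4L))        # Z first
  proj <- colSums(b, dims = 1L)           # -> T x Y x X
  if (inherits(x, "fm_series")) {
    out <- x
    out$data <- proj
    out
  } else {
    proj
  }
}

#' Convert a series to 8-bit
#'
#' Linear map of the series-global range to 0..255:
#' `v -> floor(255 * (v - min) / (max - min))`. A constant series maps to all
#' zeros. The map is monotone, so thresholding commutes with it.
#'
#' @param x an `fm_series`, array, or matrix.
#' @return Same type, integer-valued in 0..255.
#' @export
to_8bit <- function(x) {
  a <- if (inherits(x, "fm_series")) x$data else x
  stopifnot(is.numeric(a))
  lo <- min(a)
  hi <- max(a)
  out <- if (hi == lo) {
    array(0, dim(a) %||% length(a))
  } else {
    floor(255 * (a - lo) / (hi - lo))
  }
  if (!is.null(dim(a))) dim(out) <- dim(a)
  if (inherits(x, "fm_series")) {
    y <- x
    y$data <- out
    y
  } else {
    out
  }
}

# Linear (zero-padded) cross-correlation of mean-centred frames, evaluated on
# the integer shift window [-r, r]^2, via FFT. Returns the score matrix with
# dimnames giving dy (rows) and dx (cols).
shift_score_matrix <- function(frame, ref, search_radius) {
  ny <- nrow(ref)
  nx <- ncol(ref)
  r <- as.integer(search_radius)
  if (r < 0 || 2 * r + 1 > min(ny, nx)) {
    stop("search window (+/-", r, " px) does not fit inside a ",
         ny, " x ", nx, " frame")
  }
  P <- 2L * ny
  Q <- 2L * nx
  f0 <- matrix(0, P, Q)
  g0 <- matrix(0, P, Q)
  f0[seq_len(ny), seq_len(nx)] <- frame - mean(frame)
  g0[seq_len(ny), seq_len(nx)] <- ref - mean(ref)
  cc <- Re(fft(fft(f0) * Conj(fft(g0)), inverse = TRUE)) / (P * Q)
  offs_y <- -r:r
  offs_x <- -r:r
  idx <- function(o, n) ifelse(o >= 0, o + 1L, 2L * n + o + 1L)
  w <- cc[idx(offs_y, ny), idx(offs_x, nx), drop = FALSE]
  dimnames(w) <- list(dy = offs_y, dx = offs_x)
  w
}

# Deterministic argmax: highest score, ties broken by smallest |dy|+|dx|,
# then by dy, then dx.
pick_shift <- function(w) {
  offs_y <- as.integer(rownames(w))
  offs_x <- as.integer(colnames(w))
  best <- which(w == max(w), arr.ind = TRUE)
  dy <- offs_y[best[, 1]]
  dx <- offs_x[best[, 2]]
  o <- order(abs(dy) + abs(dx), dy, dx)
  c(dy = dy[o[1]], dx = dx[o[1]])
}

#' Register a projected series by integer translation
#'
#' Each frame is aligned to a reference frame (default: the last baseline
#' frame) with the integer shift that maximizes the zero-padded
#' cross-correlation of mean-centred images within `+/- search_radius`
#' pixels. Frames are translated by the negated estimated displacement;
#' pixels shifted in from outside the field are zero-filled.
#'
#' @param x an `fm_series` with 3-D data (`T x Y x X`).
#' @param reference_frame 1-based reference index; default
#'   `stim_onset_frame - 1`.
#' @param search_radius maximum shift searched, in pixels.
#' @return The registered `fm_series`, with elements `shifts` (a `T x 2`
#'   matrix of applied `(dy, dx)`) and `reference_frame` added. The shift of
#'   the reference frame is `(0, 0)` and frame shapes are unchanged.
#' @export
register_series <- function(x, reference_frame = NULL, search_radius = 8L) {
  stopifnot(inherits(x, "fm_series"), length(dim(x$data)) == 3L)
  a <- x$data
  nt <- dim(a)[1]
  if (nt < 2L) stop("registration needs at least 2 frames")
  ref_idx <- as.integer(reference_frame %||% (x$stim_onset_frame - 1L))
  if (is.na(ref_idx)) {
    stop("no reference frame: give one explicitly or set stim_onset_frame")
  }
  stopifnot(ref_idx >= 1L, ref_idx <= nt)
  ref <- a[ref_idx, , ]
  ny <- dim(a)[2]
  nx <- dim(a)[3]
  r <- as.integer(search_radius)
  if (r < 0 || 2 * r + 1 > min(ny, nx)) {
    stop("search window (+/-", r, " px) does not fit inside a ",
         ny, " x ", nx, " frame")
  }
  P <- 2L * ny
  Q <- 2L * nx
  g0 <- matrix(0, P, Q)
  g0[seq_len(ny), seq_len(nx)] <- ref - mean(ref)
  Gc <- Conj(fft(g0))                    # reference spectrum, computed once
  offs <- -r:r
  widx <- function(o, n) ifelse(o >= 0, o + 1L, 2L * n + o + 1L)
  iy <- widx(offs, ny)
  ix <- widx(offs, nx)
  shifts <- matrix(0L, nt, 2L, dimnames = list(NULL, c("dy", "dx")))
  out <- a
  f0 <- matrix(0, P, Q)
  for (t in seq_len(nt)) {
    if (t == ref_idx) next
    fr <- a[t, , ]
    f0[seq_len(ny), seq_len(nx)] <- fr - mean(fr)
    cc <- Re(fft(fft(f0) * Gc, inverse = TRUE)) / (P * Q)
    w <- cc[iy, ix, drop = FALSE]
    dimnames(w) <- list(dy = offs, dx = offs)
    d <- pick_shift(w)
    shifts[t, ] <- -d
    out[t, , ] <- translate_frame(fr, -d[["dy"]], -d[["dx"]])
  }
  y <- x
  y$data <- out
  y$shifts <- shifts
  y$reference_frame <- ref_idx
  y
}

#' Subtract the post-unloading background frame
#'
#' The background reference is the frame whose time is nearest to
#' `stimulation onset + lag_s` (default 180 s, i.e. 3 min after stimulation
#' began); an exact tie resolves to the later frame. The reference frame is
#' subtracted pixelwise from every frame and negative results are clamped to
#' zero (downstream thresholding is on positive values and 8-bit data cannot
#' represent negatives).
#'
#' @param x an `fm_series` with 3-D data.
#' @param lag_s seconds after stimulation onset at which the background
#'   reference is taken.
#' @return The subtracted `fm_series`, with element `background_frame`
#'   recording the reference index used.
#' @export
subtract_background <- function(x, lag_s = 180) {
  stopifnot(inherits(x, "fm_series"), length(dim(x$data)) == 3L)
  nt <- dim(x$data)[1]
  if (is.na(x$stim_onset_frame)) {
    stop("series lacks stimulation metadata")
  }
  if (x$stim_onset_frame > nt) {
    stop("series ends before stimulation onset")
  }
  times <- frame_times(x)
  target <- times[x$stim_onset_frame] + lag_s
  ref_idx <- nearest_frame_index(times, target)
  ref <- x$data[ref_idx, , ]
  out <- x$data
  for (t in seq_len(nt)) {
    out[t, , ] <- pmax(x$data[t, , ] - ref, 0)
  }
  y <- x
  y$data <- out
  y$background_frame <- ref_idx
  y
}
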