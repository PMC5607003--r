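# Image and tabular I/O, and the in-memory image-series container that all
# pipeline stages share.

#' Construct an image series
#'
#' An image series is the package's container for a time-lapse acquisition:
#' a numeric array of dimension `T x Z x Y x X` (raw z-stacks) or `T x Y x X`
#' (after projection), plus the acquisition constants every stage needs.
#' Frame indices are 1-based and the time of frame `k` is
#' `(k - 1) * frame_interval_s` seconds.
#'
#' @param data numeric array, `T x Z x Y x X` or `T x Y x X`.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param frame_interval_s seconds between frames (> 0).
#' @param stim_onset_frame 1-based index of the first stimulation frame; at
#'   least one baseline frame must precede it (so `>= 2`). `NA` marks a
#'   series without stimulation metadata (kinetics stages then refuse it).
#' @return An object of class `fm_series`.
#' @export
image_series <- function(data, pixel_size_um, frame_interval_s,
                         stim_onset_frame = NA) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stop("`data` must be a 3-D (T x Y x X) or 4-D (T x Z x Y x X) array")
  }
  stopifnot(is.numeric(data),
            is.numeric(pixel_size_um), pixel_size_um > 0,
            is.numeric(frame_interval_s), frame_interval_s > 0)
  stim_onset_frame <- as.integer(stim_onset_frame)
  if (!is.na(stim_onset_frame) &&
      (stim_onset_frame < 2L || stim_onset_frame > dim(data)[1])) {
    stop("`stim_onset_frame` must lie within the series and be preceded by ",
         "at least one baseline frame")
  }
  structure(
    list(data = data,
         pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s,
         stim_onset_frame = stim_onset_frame),
    class = "fm_series"
  )
}

#' @export
print.fm_series <- function(x, ...) {
  d <- dim(x$data)
  dims <- if (length(d) == 4L) {
    sprintf("T=%d, Z=%d, %d x %d px", d[1], d[2], d[3], d[4])
  } else {
    sprintf("T=%d, %d x %d px", d[1], d[2], d[3])
  }
  cat(sprintf(
    "<fm_series> %s | %.3f um/px | %.0f s/frame | stimulation onset frame %d\n",
    dims, x$pixel_size_um, x$frame_interval_s, x$stim_onset_frame))
  if (!is.null(x$shifts)) {
    cat(sprintf("  registered (reference frame %d, max |shift| %d px)\n",
                x$reference_frame, max(abs(x$shifts))))
  }
  invisible(x)
}

#' Frame times of an image series
#'
#' @param x an `fm_series`.
#' @return numeric vector, `(0:(T-1)) * frame_interval_s`.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "fm_series"))
  (seq_len(dim(x$data)[1]) - 1) * x$frame_interval_s
}

#' Write an image series (or array) to a multi-page TIFF
#'
#' Pages are written frame-major, slice-minor (`t1z1, t1z2, ..., t2z1, ...`).
#' Values are rounded to non-negative integers and stored at the requested
#' bit depth, so integer data round-trips exactly.
#'
#' @param x an `fm_series` or a numeric array (`T x Z x Y x X`, `T x Y x X`,
#'   or a single `Y x X` matrix).
#' @param path output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bits_per_sample = 16L) {
  a <- if (inherits(x, "fm_series")) x$data else x
  if (is.matrix(a)) a <- array(a, c(1L, dim(a)))
  stopifnot(is.array(a), length(dim(a)) %in% c(3L, 4L),
            bits_per_sample %in% c(8L, 16L))
  maxval <- 2^bits_per_sample - 1
  a <- round(a)
  if (any(a < 0) || any(a > maxval)) {
    stop("values outside [0, ", maxval, "] cannot be stored at ",
         bits_per_sample, " bits; rescale first")
  }
  pages <- list()
  d <- dim(a)
  if (length(d) == 3L) {
    for (t in seq_len(d[1])) pages[[t]] <- a[t, , ] / maxval
  } else {
    k <- 0L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- a[t, z, , ] / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "LZW", reduce = FALSE)
  invisible(path)
}

#' Load a multi-page TIFF as an image series
#'
#' Pages are interpreted frame-major, slice-minor with `n_z` slices per
#' timepoint (the inverse of [write_stack()]). All pages must share one
#' shape; a mismatch is rejected naming the offending page.
#'
#' @param path TIFF file.
#' @param n_z z-slices per timepoint (1 for already-projected data).
#' @param pixel_size_um,frame_interval_s,stim_onset_frame acquisition
#'   metadata attached to the returned series (see [image_series()]).
#' @return An `fm_series` with `T = n_pages / n_z`.
#' @export
load_stack <- function(path, n_z = 1L, pixel_size_um, frame_interval_s,
                       stim_onset_frame = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF contains no pages: ", path)
  ref_dim <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), ref_dim)) {
      stop(sprintf("page %d of %s has shape %s, expected %s",
                   i, path, paste(dim(pages[[i]]), collapse = "x"),
                   paste(ref_dim, collapse = "x")))
    }
  }
  n_z <- as.integer(n_z)
  if (length(pages) %% n_z != 0L) {
    stop(sprintf("%d pages is not a multiple of n_z = %d", length(pages), n_z))
  }
  nt <- length(pages) %/% n_z
  a <- array(0, c(nt, n_z, ref_dim[1], ref_dim[2]))
  k <- 0L
  for (t in seq_len(nt)) for (z in seq_len(n_z)) {
    k <- k + 1L
    a[t, z, , ] <- pages[[k]]
  }
  if (n_z == 1L) a <- array(a, c(nt, ref_dim[1], ref_dim[2]))
  image_series(a, pixel_size_um, frame_interval_s, stim_onset_frame)
}

#' Read / write an experiment manifest
#'
#' The manifest is a small JSON file tying together the image files and
#' acquisition constants of one experiment: paths to the FM stack and
#' optional eGFP/marker images, `pixel_size_um`, `frame_interval_s`, `n_z`,
#' `stim_onset_frame` (1-based), a condition label, and free-form notes.
#'
#' @param path JSON file.
#' @return A named list (class `fm_manifest`).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("fm_stack", "pixel_size_um", "frame_interval_s",
                "stim_onset_frame", "n_z")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing field(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(m$pixel_size_um > 0, m$frame_interval_s > 0,
            m$stim_onset_frame >= 2)
  structure(m, class = "fm_manifest")
}

#' @param manifest a named list of manifest fields.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write result tables and a run log
#'
#' Each table goes to `<name>.csv` with its column order preserved; a
#' `run_log.json` records the parameters, package version and seed so a run
#' can be reproduced. Reruns on identical inputs produce byte-identical CSVs
#' (only the run-log timestamp differs).
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param run_info named list echoed into the run log (parameters, seed, ...).
#' @return Paths of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir, run_info = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log <- list(
    package = "fmdestain",
    version = as.character(packageVersion("fmdestain")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    run_info = run_info
  )
  lp <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, lp))
}
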