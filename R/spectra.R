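## Query-side inputs: full spectra as (ppm, intensity) traces, or externally
## determined peak lists.  Spectra are denoised by an intensity threshold and
## peaks picked as local maxima; inputs are assumed already Fourier
## transformed, phased and baseline corrected.

new_raw_spectrum <- function(ppm, intensity) {
  structure(tibble(ppm = ppm, intensity = intensity),
            class = c("raw_spectrum", class(tibble())))
}

new_peak_list <- function(peaks, origin = c("user-supplied", "picked-from-spectrum"),
                          eta = NA_real_) {
  origin <- match.arg(origin)
  structure(peaks, origin = origin, eta = eta,
            class = c("peak_list", class(tibble())))
}

#' Coerce peaks to a query peak list
#'
#' @param x A two-column data frame (`ppm`, `height`) or numeric vector of ppm
#'   values (unit heights).
#' @return A `peak_list` tibble with canonical, unique ppm.
#' @export
as_peak_list <- function(x) {
  if (inherits(x, "peak_list")) return(x)
  if (is.numeric(x)) x <- peak_tbl(x)
  if (is.data.frame(x)) x <- peak_tbl(x$ppm, if ("height" %in% names(x)) x$height else 1)
  new_peak_list(x, origin = "user-supplied")
}

#' Read a full spectrum from two-column ASCII
#'
#' The file must contain two numeric columns, chemical shift (ppm) and signal
#' intensity, whitespace- or comma-separated; `#` comment lines and blank
#' lines are skipped.  Files written with the conventional descending NMR
#' ppm axis are accepted and re-sorted to ascending ppm.
#'
#' @param path File to read.
#' @return A `raw_spectrum` tibble (`ppm`, `intensity`) sorted by ascending
#'   ppm, with at least 3 points.
#' @export
read_spectrum <- function(path) {
  d <- read_two_columns(path, min_rows = 3L)
  if (any(!is.finite(d$y))) {
    abort(sprintf("%s: intensities must be finite.", path),
          class = "specmatch_parse_error")
  }
  ord <- order(d$x)
  new_raw_spectrum(d$x[ord], d$y[ord])
}

#' Read an externally determined peak list
#'
#' Two numeric columns: ppm and height.  Peaks are canonicalized to the
#' 0.01 ppm grid; coordinates that collide after canonicalization are
#' collapsed keeping the larger height.  An empty file yields an empty peak
#' list.
#'
#' @param path File to read.
#' @return A `peak_list` with `origin = "user-supplied"`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("peak list '%s' does not exist.", path),
          class = "specmatch_io_error")
  }
  d <- read_two_columns(path)
  if (!length(d$x)) {
    return(new_peak_list(tibble(ppm = numeric(), height = numeric())))
  }
  new_peak_list(peak_tbl(d$x, d$y, warn_duplicates = TRUE))
}

#' Pick peaks from a spectrum above a noise threshold
#'
#' Data points with intensity below the noise threshold `eta` are removed
#' (the comparison is inclusive: points at exactly `eta` are kept), and peaks
#' are the local maxima of the surviving intensity sequence taken in ppm
#' order.  A plateau of equal maximal intensities yields a single peak at the
#' plateau's central ppm.  Peak positions are canonicalized to the 0.01 ppm
#' grid; heights are preserved.
#'
#' @param spec A [read_spectrum()] result (or any data frame with `ppm` and
#'   `intensity` columns).
#' @param eta Noise threshold intensity, `>= 0`.  A threshold above the
#'   global maximum yields an empty peak list (downstream searches decide how
#'   to treat that).
#' @return A `peak_list` with `origin = "picked-from-spectrum"`.
#' @export
pick_peaks <- function(spec, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0) {
    abort("`eta` must be a single nonnegative number.",
          class = "specmatch_config_error")
  }
  stopifnot(is.data.frame(spec), all(c("ppm", "intensity") %in% names(spec)))
  ord <- order(spec$ppm)
  ppm <- spec$ppm[ord]
  y <- spec$intensity[ord]
  keep <- y >= eta
  ppm <- ppm[keep]; y <- y[keep]
  if (!length(y)) {
    return(new_peak_list(tibble(ppm = numeric(), height = numeric()),
                         origin = "picked-from-spectrum", eta = eta))
  }
  ## collapse runs of equal consecutive intensity into plateaus
  run_id <- cumsum(c(TRUE, y[-1] != y[-length(y)]))
  run_val <- as.numeric(tapply(y, run_id, function(v) v[1]))
  run_lo <- as.numeric(tapply(ppm, run_id, min))
  run_hi <- as.numeric(tapply(ppm, run_id, max))
  nr <- length(run_val)
  left <- c(-Inf, run_val[-nr])
  right <- c(run_val[-1], -Inf)
  is_max <- run_val > left & run_val > right
  out <- peak_tbl(ppm = (run_lo[is_max] + run_hi[is_max]) / 2,
                  height = as.numeric(run_val[is_max]))
  new_peak_list(out, origin = "picked-from-spectrum", eta = eta)
}

#' Write a peak list or spectrum as two-column text
#'
#' @param x A `peak_list` or `raw_spectrum` (any two-column data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_two_columns <- function(x, path) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s",
                     formatC(x[[1]], format = "g", digits = 17),
                     formatC(x[[2]], format = "g", digits = 17)),
             con)
  invisible(path)
}
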