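## Seedable generators: reference libraries with controllable cross-record
## peak overlap, random mixtures, the two noise channels used for
## benchmarking (random peak removal, +/- chemical-shift perturbation), and
## a Lorentzian spectrum renderer so the peak picker can be exercised on
## full spectra.  All generators are pure functions of (parameters, seed);
## with seed = NULL they consume the caller's RNG stream instead.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate a synthetic reference library
#'
#' Emulates the shape of curated 1H reference libraries: per-record peak
#' counts drawn uniformly from a range (real libraries span roughly 1-181
#' peaks per metabolite for HMDB-derived lists and 1-66 for MMCD-derived
#' ones), coordinates on the 0.01 ppm grid, and a tunable degree of
#' cross-metabolite peak sharing.  Each peak coordinate is drawn from a
#' shared pool with probability `overlap_rate` (creating the overlap
#' structure real libraries show), otherwise from the grid coordinates not
#' yet used by any record — so `overlap_rate = 0` yields pairwise-disjoint
#' records.
#'
#' @param k Number of records, `>= 1`.
#' @param peak_count_range Integer range `c(min, max)` for per-record peak
#'   counts.  Default `c(1, 181)`, the HMDB-like span.
#' @param ppm_range Chemical-shift window, default `c(0, 10)` (typical 1H).
#' @param overlap_rate Probability a peak coordinate comes from the shared
#'   pool; default 0.25.
#' @param shared_pool_size Size of the shared coordinate pool (default 200).
#' @param source Provenance label stored on every record.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @return A [ref_library()] with ids `SYN0001`, `SYN0002`, ...; metadata
#'   sampled from the controlled vocabularies.
#' @export
generate_library <- function(k, peak_count_range = c(1, 181),
                             ppm_range = c(0, 10), overlap_rate = 0.25,
                             shared_pool_size = 200, source = "user",
                             seed = NULL) {
  if (!is.numeric(k) || k < 1) {
    abort("`k` must be >= 1.", class = "specmatch_config_error")
  }
  pcr <- as.integer(peak_count_range)
  if (length(pcr) != 2L || pcr[1] < 1L || pcr[1] > pcr[2]) {
    abort("`peak_count_range` must satisfy 1 <= min <= max.",
          class = "specmatch_config_error")
  }
  if (overlap_rate < 0 || overlap_rate > 1) {
    abort("`overlap_rate` must lie in [0, 1].", class = "specmatch_config_error")
  }
  grid <- seq(cppm(ppm_range[1]), cppm(ppm_range[2]))
  if (length(grid) < 2L) {
    abort("`ppm_range` is too narrow for the 0.01 ppm grid.",
          class = "specmatch_config_error")
  }
  with_seed_maybe(seed, {
    pool <- sample(grid, min(shared_pool_size, length(grid)))
    used <- integer(0)
    records <- vector("list", k)
    for (i in seq_len(k)) {
      n_pk <- sample(seq(pcr[1], pcr[2]), 1L)
      coords <- integer(0)
      for (j in seq_len(n_pk)) {
        from_pool <- overlap_rate > 0 && runif(1) < overlap_rate
        if (from_pool) {
          avail <- setdiff(pool, coords)
          if (!length(avail)) from_pool <- FALSE
        }
        if (from_pool) {
          coords <- c(coords, sample(avail, 1L))
        } else {
          avail <- setdiff(grid, c(used, coords))
          if (!length(avail)) {
            abort(paste("ppm grid exhausted: reduce k or peak counts,",
                        "widen `ppm_range`, or raise `overlap_rate`."),
                  class = "specmatch_config_error")
          }
          fresh <- if (length(avail) == 1L) avail else sample(avail, 1L)
          coords <- c(coords, fresh)
          used <- c(used, fresh)
        }
      }
      records[[i]] <- metabolite_record(
        id = sprintf("SYN%04d", i),
        name = sprintf("synthetic metabolite %d", i),
        peaks = peak_tbl(coords / 100, height = round(runif(n_pk, 0.1, 10), 4)),
        source = source,
        mtype = sample(mtype_levels, 1L),
        ph = round(runif(1, ph_range_allowed[1], ph_range_allowed[2]), 2),
        solvent = sample(solvent_levels, 1L),
        frequency = sample(frequency_levels, 1L)
      )
    }
    ref_library(records)
  })
}

#' Pool a random mixture from a library
#'
#' Samples `n` distinct records uniformly without replacement and pools
#' their peaks (canonical union; at a shared coordinate the larger height is
#' kept).
#'
#' @param lib A [ref_library()].
#' @param n Mixture size, `1 <= n <= library_size(lib)`.
#' @param seed RNG seed or `NULL`.
#' @return A `mixture_truth` list: `member_ids` (sorted) and `pooled_peaks`
#'   (a `peak_list`).
#' @export
make_mixture <- function(lib, n, seed = NULL) {
  stopifnot(inherits(lib, "ref_library"))
  k <- nrow(lib)
  if (!is.numeric(n) || n < 1 || n > k) {
    abort(sprintf("`n` must lie in [1, %d].", k),
          class = "specmatch_config_error")
  }
  with_seed_maybe(seed, {
    idx <- sample.int(k, n)
    members <- sort(lib$id[idx])
    pooled <- dplyr::bind_rows(lib$peaks[idx])
    structure(list(member_ids = members,
                   pooled_peaks = as_peak_list(peak_tbl(pooled$ppm, pooled$height))),
              class = "mixture_truth")
  })
}

#' @export
print.mixture_truth <- function(x, ...) {
  cat(sprintf("# Mixture of %d metabolites, %d pooled peaks\n",
              length(x$member_ids), nrow(x$pooled_peaks)))
  cat("members:", paste(x$member_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Inject benchmark noise into a peak set
#'
#' The two noise channels used throughout the benchmarking experiments:
#' first `floor(remove_fraction * count)` peaks are deleted uniformly at
#' random, then every survivor is shifted by `+shift_magnitude` or
#' `-shift_magnitude` with equal, per-peak independent probability and
#' re-canonicalized (colliding coordinates collapse, keeping the larger
#' height).
#'
#' @param peaks A peak table or numeric ppm vector.
#' @param remove_fraction Fraction of peaks to delete, in `[0, 0.5]`.
#' @param shift_magnitude ppm perturbation, one of 0, 0.01, ..., 0.05.
#' @param seed RNG seed or `NULL`.
#' @return A `peak_list` of the surviving, perturbed peaks.
#' @export
apply_noise <- function(peaks, remove_fraction = 0, shift_magnitude = 0,
                        seed = NULL) {
  if (remove_fraction < 0 || remove_fraction > 0.5) {
    abort("`remove_fraction` must lie in [0, 0.5].",
          class = "specmatch_config_error")
  }
  allowed <- c(0, 0.01, 0.02, 0.03, 0.04, 0.05)
  if (!any(abs(shift_magnitude - allowed) < 1e-12)) {
    abort("`shift_magnitude` must be one of 0, 0.01, ..., 0.05.",
          class = "specmatch_config_error")
  }
  pk <- if (is.data.frame(peaks)) peak_tbl(peaks$ppm, peaks$height) else peak_tbl(peaks)
  with_seed_maybe(seed, {
    n <- nrow(pk)
    n_drop <- floor(remove_fraction * n)
    if (n_drop > 0) pk <- pk[-sample.int(n, n_drop), , drop = FALSE]
    if (shift_magnitude > 0 && nrow(pk)) {
      signs <- sample(c(-1, 1), nrow(pk), replace = TRUE)
      pk$ppm <- pk$ppm + signs * shift_magnitude
    }
    as_peak_list(peak_tbl(pk$ppm, pk$height))
  })
}

#' Render a peak set as a synthetic spectrum
#'
#' Sums Lorentzian lines (the natural NMR lineshape) centred at each peak,
#' with the peak height as apex amplitude and a common full width at half
#' maximum, adds Gaussian baseline noise, and samples the result on a
#' uniform ppm grid.
#'
#' @param peaks A peak table or numeric ppm vector (unit heights).
#' @param linewidth Full width at half maximum in ppm (default 0.02).
#' @param grid_step Grid spacing in ppm; must be `<= linewidth / 4` so lines
#'   are resolved on the grid.  Default `linewidth / 10`.
#' @param noise_sd Standard deviation of the Gaussian baseline noise
#'   (default 0).
#' @param ppm_range Window to render; defaults to the peak span padded by 20
#'   linewidths (or `c(0, 10)` when `peaks` is empty).
#' @param seed RNG seed or `NULL` (used only when `noise_sd > 0`).
#' @return A `raw_spectrum` tibble.
#' @export
render_spectrum <- function(peaks, linewidth = 0.02, grid_step = linewidth / 10,
                            noise_sd = 0, ppm_range = NULL, seed = NULL) {
  pk <- if (is.data.frame(peaks)) peak_tbl(peaks$ppm, peaks$height) else {
    if (length(peaks)) peak_tbl(peaks) else tibble(ppm = numeric(), height = numeric())
  }
  if (grid_step <= 0 || grid_step > linewidth / 4) {
    abort("`grid_step` must be positive and <= linewidth / 4.",
          class = "specmatch_config_error")
  }
  if (is.null(ppm_range)) {
    ppm_range <- if (nrow(pk)) range(pk$ppm) + c(-20, 20) * linewidth else c(0, 10)
  }
  grid <- seq(ppm_range[1], ppm_range[2], by = grid_step)
  if (length(grid) < 3L) {
    abort("rendering grid has fewer than 3 points; widen `ppm_range`.",
          class = "specmatch_config_error")
  }
  hw2 <- (linewidth / 2)^2
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(pk))) {
    y <- y + pk$height[i] * hw2 / ((grid - pk$ppm[i])^2 + hw2)
  }
  if (noise_sd > 0) {
    y <- y + with_seed_maybe(seed, stats::rnorm(length(grid), sd = noise_sd))
  }
  new_raw_spectrum(grid, y)
}
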