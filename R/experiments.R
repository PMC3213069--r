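## Benchmark drivers: metabolite recovery from random mixtures, degradation
## under the two noise channels, and the f1-vs-f2 scoring-function
## comparison.  All return tidy tibbles (one row per condition x method)
## suitable for autoplot().

#' Recovery of randomly pooled metabolites
#'
#' For each mixture size `n`, pools `runs` random `n`-member mixtures and
#' searches them, recording the percentage of members recovered (a)
#' anywhere in the result list ("ALL") and (b) within the first `n` ranks
#' ("TOPN"), averaged over runs.
#'
#' @param lib A [ref_library()].
#' @param n_range Mixture sizes to sweep (default `1:10`).
#' @param runs Random mixtures per size (default 25).
#' @param methods Search methods to compare (default MH1 and MH3).
#' @param r Confidence threshold used by the searches (default 0.5).
#' @param all_unthresholded If `TRUE` (default) the "ALL" percentage counts
#'   a member found at any rank with no score threshold (`r = 0`, uncapped
#'   list); if `FALSE` it uses the same thresholded list as "TOPN".
#' @param seed RNG seed or `NULL`.
#' @return A `recovery_experiment` tibble: `n`, `method`, `all_pct`,
#'   `topn_pct`, `runs`.
#' @export
recovery_experiment <- function(lib, n_range = 1:10, runs = 25,
                                methods = c("MH1", "MH3"), r = 0.5,
                                all_unthresholded = TRUE, seed = NULL) {
  stopifnot(inherits(lib, "ref_library"), runs >= 1)
  k <- nrow(lib)
  with_seed_maybe(seed, {
    grid <- tidyr::expand_grid(n = n_range, run = seq_len(runs))
    per_run <- purrr::pmap_dfr(grid, function(n, run) {
      mix <- make_mixture(lib, n)
      purrr::map_dfr(methods, function(m) {
        res_top <- search_library(mix$pooled_peaks, lib, method = m, r = r,
                                  max_results = k)
        res_all <- if (all_unthresholded) {
          search_library(mix$pooled_peaks, lib, method = m, r = 0,
                         max_results = k)
        } else res_top
        tibble(
          n = n, method = m,
          all_pct = 100 * mean(mix$member_ids %in% res_all$metabolite_id),
          topn_pct = 100 * mean(mix$member_ids %in% head(res_top$metabolite_id, n))
        )
      })
    })
    out <- per_run |>
      dplyr::group_by(.data$n, .data$method) |>
      dplyr::summarise(all_pct = mean(.data$all_pct),
                       topn_pct = mean(.data$topn_pct), .groups = "drop") |>
      dplyr::mutate(runs = runs)
    structure(out, class = c("recovery_experiment", class(out)))
  })
}

#' Identification under spectral noise
#'
#' Sweeps the two noise channels — random peak removal and +/- chemical
#' shift perturbation — and reports the mean percentage of metabolites still
#' identified at each level.  Two protocols:
#'
#' * `mode = "single"`: every library record is individually noised and
#'   searched against the full library, `reps` times; a record counts as
#'   identified if it appears within the first `within_first` results.
#' * `mode = "pooled"`: `reps` random `pool_size`-member mixtures are built,
#'   noise applied to each member's peaks before pooling, and a member
#'   counts as identified if it is reported within the first `within_first`
#'   results.
#'
#' MH2 is run with its tolerance set equal to the current shift magnitude
#' (the protocol assumes the tolerance approximates the true shift); at the
#' removal-only conditions that tolerance is 0, where MH2 coincides with
#' MH1.
#'
#' @param lib A [ref_library()].
#' @param remove_fractions Removal levels to sweep (default
#'   `seq(0, 0.5, 0.1)`); each is paired with shift 0.
#' @param shift_magnitudes Shift levels to sweep (default
#'   `seq(0, 0.05, 0.01)`); each is paired with removal 0.
#' @param mode `"single"` or `"pooled"`.
#' @param pool_size Mixture size for pooled mode (default 50).
#' @param reps Repetitions per condition (default 5 for single mode, 50 for
#'   pooled in the full protocol; pass a smaller value for quick runs).
#' @param methods Methods to compare (default all three).
#' @param within_first Reporting cap defining a successful match (default
#'   50).
#' @param r Confidence threshold (default 0.5).
#' @param seed RNG seed or `NULL`.
#' @return A `noise_experiment` tibble: `noise`, `level`, `method`, `mode`,
#'   `mean_pct`, `reps`.
#' @export
noise_experiment <- function(lib,
                             remove_fractions = seq(0, 0.5, by = 0.1),
                             shift_magnitudes = seq(0, 0.05, by = 0.01),
                             mode = c("single", "pooled"), pool_size = 50,
                             reps = if (mode == "single") 5 else 50,
                             methods = c("MH1", "MH2", "MH3"),
                             within_first = 50, r = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "ref_library"))
  conditions <- dplyr::bind_rows(
    tibble(noise = "remove", level = remove_fractions, rf = remove_fractions,
           sm = 0),
    tibble(noise = "shift", level = shift_magnitudes, rf = 0,
           sm = shift_magnitudes)
  ) |> dplyr::distinct()
  run_one <- function(sample, truth, meth, tol) {
    res <- search_library(sample, lib, method = meth, r = r,
                          tolerance = if (meth == "MH2") tol else 0,
                          max_results = within_first)
    100 * mean(truth %in% res$metabolite_id)
  }
  with_seed_maybe(seed, {
    out <- purrr::pmap_dfr(conditions, function(noise, level, rf, sm) {
      purrr::map_dfr(seq_len(reps), function(rep) {
        if (mode == "single") {
          purrr::map_dfr(seq_len(nrow(lib)), function(i) {
            noised <- apply_noise(lib$peaks[[i]], rf, sm)
            if (nrow(noised) == 0L) {
              return(tibble(method = methods, pct = 0))
            }
            tibble(method = methods,
                   pct = vapply(methods, function(m)
                     run_one(noised, lib$id[i], m, sm), numeric(1)))
          })
        } else {
          mix <- make_mixture(lib, pool_size)
          idx <- match(mix$member_ids, lib$id)
          pooled <- dplyr::bind_rows(
            lapply(idx, function(i) apply_noise(lib$peaks[[i]], rf, sm))
          )
          pooled <- as_peak_list(peak_tbl(pooled$ppm, pooled$height))
          tibble(method = methods,
                 pct = vapply(methods, function(m)
                   run_one(pooled, mix$member_ids, m, sm), numeric(1)))
        }
      }) |>
        dplyr::group_by(.data$method) |>
        dplyr::summarise(mean_pct = mean(.data$pct), .groups = "drop") |>
        dplyr::mutate(noise = noise, level = level, mode = mode, reps = reps,
                      .before = 1)
    })
    out <- out[, c("noise", "level", "method", "mode", "mean_pct", "reps")]
    structure(out, class = c("noise_experiment", class(out)))
  })
}

#' Scoring-function comparison by self-query
#'
#' Queries every library record's own peak list against the library and
#' reports top-1 identification accuracy under the default score
#' (`matched / (total + 1)`, "f2") versus the plain match fraction
#' (`matched / total`, "f1") used by simpler fingerprinting tools.  The +1
#' denominator breaks the ties f1 creates between a full record and records
#' whose peaks are a perfectly matched subset of the query.
#'
#' @param lib A [ref_library()].
#' @param method Search method (default `"MH1"`).
#' @param r Confidence threshold used for the searches (default 0, so
#'   rank 1 is always defined when any peak matches).
#' @return A `scoring_comparison` tibble: `score_fn`, `top1_pct`, `k`.
#' @export
scoring_comparison <- function(lib, method = "MH1", r = 0) {
  stopifnot(inherits(lib, "ref_library"))
  hit <- function(fn) {
    mean(vapply(seq_len(nrow(lib)), function(i) {
      res <- search_library(lib$peaks[[i]], lib, method = method, r = r,
                            score_fn = fn, max_results = 1)
      nrow(res) >= 1L && res$metabolite_id[1] == lib$id[i]
    }, logical(1)))
  }
  out <- tibble(score_fn = c("f1", "f2"),
                top1_pct = 100 * c(hit("f1"), hit("f2")),
                k = nrow(lib))
  structure(out, class = c("scoring_comparison", class(out)))
}
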