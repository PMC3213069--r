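## Search engine: the significance score, exact and shift-tolerant peak
## matching, and the three search strategies
##   MH1 - exact coordinate matching (tolerance forced to 0),
##   MH2 - matching inside a +/- tolerance window,
##   MH3 - greedy selection with mutual exclusion of peaks: the best-scoring
##         metabolite is emitted and its matched sample coordinates removed
##         before re-scoring the remainder.

#' Significance score for a candidate metabolite
#'
#' The ranking statistic used by all search methods: the number of matched
#' library peaks divided by one plus the total number of library peaks.
#' Unlike the plain matched/total fraction used by several other
#' fingerprinting tools, the +1 in the denominator makes peak-rich
#' metabolites score strictly higher at an equal match fraction: 2 of 4
#' peaks scores 0.40 while 5 of 10 scores 0.45.
#'
#' @param matched Number of matched library peaks (vectorized).
#' @param total Total number of library peaks (`>= 1`).
#' @param fn `"f2"` for the default score `matched / (total + 1)`; `"f1"` for
#'   the plain fraction `matched / total`, provided for scoring-function
#'   comparisons.
#' @return Numeric score in `[0, 1)` (for `"f2"`); full precision.  Display
#'   rounding to two decimals happens only at output.
#' @examples
#' significance_score(2, 4)   # 0.4
#' significance_score(5, 10)  # 0.4545...
#' @export
significance_score <- function(matched, total, fn = c("f2", "f1")) {
  fn <- match.arg(fn)
  if (any(total < 1) || any(matched < 0)) {
    abort("need total >= 1 and matched >= 0.", class = "specmatch_logic_error")
  }
  if (any(matched > total)) {
    abort("matched cannot exceed total.", class = "specmatch_logic_error")
  }
  if (fn == "f2") matched / (total + 1) else matched / total
}

#' Count library peaks matched by a sample
#'
#' A library peak `q` counts as matched iff some sample peak `p` satisfies
#' `|q - p| <= tolerance` (inclusive window); each library peak contributes
#' at most once regardless of how many sample peaks fall in its window.
#' Tolerance 0 means exact canonical equality.  Peak heights play no role.
#'
#' @param record_peaks Numeric vector (or peak table) of canonical library
#'   peak positions.
#' @param sample Numeric vector (or peak table) of canonical sample peak
#'   positions.
#' @param tolerance Shift tolerance in ppm, `>= 0`.
#' @return List with `matched` (count) and `coords` (the matched library
#'   coordinates, ascending).
#' @export
count_matches <- function(record_peaks, sample, tolerance = 0) {
  q <- if (is.data.frame(record_peaks)) record_peaks$ppm else record_peaks
  p <- if (is.data.frame(sample)) sample$ppm else sample
  hit <- matched_lib_peaks(cppm(q), cppm(p), tolerance)
  list(matched = sum(hit), coords = sort(q[hit]))
}

## coordinate comparison on the integer centi-ppm grid; the tolerance is
## converted with a representation guard so that e.g. 0.01 covers exactly
## one grid step.  `other` must be sorted ascending; an element x matches
## iff some element of `other` lies in [x - tol, x + tol] (inclusive).
window_hit <- function(x, other_sorted, tolerance) {
  if (!length(x)) return(logical(0))
  if (!length(other_sorted)) return(rep(FALSE, length(x)))
  tol_c <- tolerance * 100 + 1e-9
  findInterval(x + tol_c, other_sorted) -
    findInterval(x - tol_c - 0.5, other_sorted) > 0
}

matched_lib_peaks <- function(qi, pi, tolerance) {
  window_hit(qi, sort(pi), tolerance)
}

## sample coordinates consumed by a matched record (MH3 removal step):
## every sample peak inside the window of any matched library peak
consumed_sample_peaks <- function(qi_matched, pi, tolerance) {
  window_hit(pi, sort(qi_matched), tolerance)
}

#' Search configuration
#'
#' Bundles the knobs shared by the search methods.
#'
#' @param method One of `"MH1"`, `"MH2"`, `"MH3"`.
#' @param eta Noise threshold applied to the sample peaks before matching
#'   (peaks with height below `eta` are dropped).
#' @param r Confidence/ranking threshold in `[0, 1]`; a metabolite is
#'   reported only if its score is at least `r` (inclusive).  Default 0.5.
#' @param tolerance Shift tolerance in ppm (default 0).  MH1 requires 0.
#' @param features Metadata filters passed to [filter_records()].
#' @param max_results Output cap (default 100).
#' @param score_fn `"f2"` (default) or `"f1"`, see [significance_score()].
#' @param experimental_drift Opt-in for MH3 with nonzero tolerance; the
#'   windowed removal rule is experimental (see Details in [search_mh3()]).
#' @return A `search_config` list.
#' @export
search_config <- function(method = c("MH1", "MH2", "MH3"), eta = 0, r = 0.5,
                          tolerance = 0, features = list(), max_results = 100,
                          score_fn = c("f2", "f1"),
                          experimental_drift = FALSE) {
  method <- match.arg(method)
  score_fn <- match.arg(score_fn)
  if (!is.numeric(r) || r < 0 || r > 1) {
    abort("`r` must lie in [0, 1].", class = "specmatch_config_error")
  }
  if (!is.numeric(tolerance) || tolerance < 0) {
    abort("`tolerance` must be >= 0.", class = "specmatch_config_error")
  }
  if (method == "MH1" && tolerance > 0) {
    abort("MH1 performs exact matching; `tolerance` must be 0.",
          class = "specmatch_config_error")
  }
  if (method == "MH3" && tolerance > 0 && !isTRUE(experimental_drift)) {
    abort(paste("MH3 with nonzero tolerance uses windowed peak removal,",
                "which is experimental; set `experimental_drift = TRUE`",
                "to opt in."),
          class = "specmatch_config_error")
  }
  if (!is.numeric(eta) || eta < 0) {
    abort("`eta` must be >= 0.", class = "specmatch_config_error")
  }
  if (!is.numeric(max_results) || max_results < 1) {
    abort("`max_results` must be >= 1.", class = "specmatch_config_error")
  }
  structure(list(method = method, eta = eta, r = r, tolerance = tolerance,
                 features = features, max_results = max_results,
                 score_fn = score_fn,
                 experimental_drift = isTRUE(experimental_drift)),
            class = "search_config")
}

prepare_search <- function(sample, lib, cfg) {
  sample <- as_peak_list(sample)
  if (cfg$eta > 0 && nrow(sample)) {
    sample <- new_peak_list(sample[sample$height >= cfg$eta, , drop = FALSE],
                            origin = attr(sample, "origin") %||% "user-supplied",
                            eta = cfg$eta)
  }
  if (nrow(sample) == 0L) {
    abort("the sample contains no peaks above the noise threshold.",
          class = "specmatch_empty_input")
  }
  lib <- filter_records(lib, cfg$features)
  if (nrow(lib) == 0L) {
    abort("no library records satisfy the feature filters.",
          class = "specmatch_config_error")
  }
  list(sample = sample, lib = lib)
}

score_all <- function(lib, sample_cppm, tolerance, score_fn, qlist = NULL) {
  if (is.null(qlist)) qlist <- lapply(lib$peaks, function(pk) cppm(pk$ppm))
  pis <- sort(sample_cppm)
  hits <- lapply(qlist, function(qi) qi[window_hit(qi, pis, tolerance)])
  matched <- lengths(hits)
  total <- lengths(qlist)
  tibble(
    metabolite_id = lib$id,
    name = lib$name,
    score = significance_score(matched, total, fn = score_fn),
    matched = matched,
    total = total,
    matched_coords = lapply(hits, function(h) sort(h) / 100)
  )
}

#' Order scored candidates and assign ranks
#'
#' Sorts by descending full-precision score, breaking ties by more matched
#' peaks, then lexicographic metabolite id; assigns 1-based ranks and
#' truncates at the output cap.
#'
#' @param results Tibble of scored candidates (as built by the searches).
#' @param max_results Output cap.
#' @return The ranked, truncated tibble with a `rank` column.
#' @export
rank_results <- function(results, max_results = 100) {
  out <- results[order(-results$score, -results$matched, results$metabolite_id), ,
                 drop = FALSE]
  out <- head(out, max_results)
  out$rank <- seq_len(nrow(out))
  out
}

finalize_result <- function(results, cfg, lib, sample) {
  meta <- as_tibble(lib)[, c("id", "source", "mtype", "ph", "solvent", "frequency")]
  out <- dplyr::left_join(results, meta, by = c(metabolite_id = "id"))
  out <- out[, c("rank", "metabolite_id", "name", "score", "matched", "total",
                 "matched_coords", "source", "mtype", "ph", "solvent",
                 "frequency")]
  structure(out,
            config = cfg, k = nrow(lib), n_sample_peaks = nrow(sample),
            class = c("mh_result", class(tibble())))
}

#' Exact-matching search (MH1)
#'
#' Scores every library record (after metadata filtering) against the sample
#' with exact canonical matching, keeps records whose score is at least
#' `cfg$r`, and returns them ranked by descending score.
#'
#' @param sample A `peak_list` (or anything [as_peak_list()] accepts); must
#'   be nonempty after the noise threshold.
#' @param lib A [ref_library()].
#' @param cfg A [search_config()]; its `method` must agree with the function
#'   called.  The convenience arguments `...` override config fields.
#' @param ... Overrides forwarded to [search_config()].
#' @return An `mh_result` tibble: `rank`, `metabolite_id`, `name`, `score`
#'   (full precision), `matched`, `total`, `matched_coords` (list-column of
#'   matched library coordinates), and the record metadata.
#' @examples
#' lib <- ref_library(list(
#'   metabolite_record("A", peaks = c(1.00, 2.00, 3.00)),
#'   metabolite_record("B", peaks = 1.00),
#'   metabolite_record("C", peaks = c(5.00, 6.00))
#' ))
#' search_mh1(c(1.00, 2.00, 3.00), lib)
#' @export
search_mh1 <- function(sample, lib, cfg = search_config("MH1"), ...) {
  cfg <- override_config(cfg, "MH1", ...)
  run_flat_search(sample, lib, cfg)
}

#' Shift-tolerant search (MH2)
#'
#' Identical to [search_mh1()] except that a library peak matches any sample
#' peak within `+/- tolerance` ppm (inclusive).  With `tolerance = 0` the
#' output equals MH1's exactly.
#'
#' @inheritParams search_mh1
#' @return An `mh_result` tibble; see [search_mh1()].
#' @export
search_mh2 <- function(sample, lib, cfg = search_config("MH2"), ...) {
  cfg <- override_config(cfg, "MH2", ...)
  run_flat_search(sample, lib, cfg)
}

override_config <- function(cfg, method, ...) {
  dots <- list(...)
  base <- unclass(cfg)
  base$method <- method
  do.call(search_config, modifyList(base, dots))
}

run_flat_search <- function(sample, lib, cfg) {
  pre <- prepare_search(sample, lib, cfg)
  scored <- score_all(pre$lib, cppm(pre$sample$ppm), cfg$tolerance, cfg$score_fn)
  kept <- scored[scored$score >= cfg$r & scored$matched >= 1L, , drop = FALSE]
  finalize_result(rank_results(kept, cfg$max_results), cfg, pre$lib, pre$sample)
}

#' Greedy mutually-exclusive search (MH3)
#'
#' Iteratively selects the best-scoring library record against the
#' *remaining* sample peaks, emits it if its score reaches `cfg$r`, and
#' removes the sample coordinates it matched before re-scoring the rest.
#' Selection ties go to the record with more peaks, then the
#' lexicographically smaller id.  The iteration stops when the sample or the
#' candidate pool is exhausted, or when the best remaining candidate either
#' falls below `r` or matches no remaining peak (residual peaks that no
#' record explains are left unassigned).
#'
#' Early selections consume shared coordinates, so overlapping metabolites
#' lower each other's later scores: this suppresses false positives at the
#' cost of extra false negatives.  With nonzero tolerance the removal takes
#' every remaining sample peak inside a matched library peak's window; that
#' rule is experimental and requires `experimental_drift = TRUE`.
#'
#' @inheritParams search_mh1
#' @return An `mh_result` tibble in *selection order* (rank = selection
#'   order), with attribute `unassigned`: the sample coordinates left
#'   unexplained.
#' @export
search_mh3 <- function(sample, lib, cfg = search_config("MH3"), ...) {
  cfg <- override_config(cfg, "MH3", ...)
  pre <- prepare_search(sample, lib, cfg)
  lib <- pre$lib
  remaining <- cppm(pre$sample$ppm)
  qlist <- lapply(lib$peaks, function(pk) cppm(pk$ppm))
  candidates <- rep(TRUE, nrow(lib))
  picks <- list()
  while (length(remaining) && any(candidates)) {
    idx <- which(candidates)
    sub <- as_tibble(lib)[idx, , drop = FALSE]
    scored <- score_all(sub, remaining, cfg$tolerance, cfg$score_fn,
                        qlist = qlist[idx])
    ## selection tie-break: score, then total peak count, then id
    ord <- order(-scored$score, -scored$total, scored$metabolite_id)
    best <- scored[ord[1], ]
    if (best$score < cfg$r || best$matched < 1L) break
    picks <- c(picks, list(best))
    consumed <- consumed_sample_peaks(cppm(best$matched_coords[[1]]),
                                      remaining, cfg$tolerance)
    remaining <- remaining[!consumed]
    candidates[idx[ord[1]]] <- FALSE
  }
  out <- if (length(picks)) dplyr::bind_rows(picks) else
    score_all(as_tibble(lib)[0, , drop = FALSE], remaining, 0, cfg$score_fn)
  out <- head(out, cfg$max_results)
  out$rank <- seq_len(nrow(out))
  res <- finalize_result(out, cfg, lib, pre$sample)
  attr(res, "unassigned") <- sort(remaining) / 100
  res
}

#' Run a search by method name
#'
#' Dispatches to [search_mh1()], [search_mh2()] or [search_mh3()].
#'
#' @inheritParams search_mh1
#' @param method `"MH1"`, `"MH2"` or `"MH3"`.
#' @return An `mh_result` tibble.
#' @export
search_library <- function(sample, lib, method = c("MH1", "MH2", "MH3"), ...) {
  method <- match.arg(method)
  fn <- switch(method, MH1 = search_mh1, MH2 = search_mh2, MH3 = search_mh3)
  fn(sample, lib, cfg = search_config(method, ...))
}

#' Write search results as TSV
#'
#' Columns mirror a typical results view: rank, id, name, two-decimal display
#' score, full-precision score, matched/total, and the record metadata.
#'
#' @param res An `mh_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(res, path) {
  out <- data.frame(
    rank = res$rank, metabolite_id = res$metabolite_id, name = res$name,
    score = sprintf("%.2f", res$score),
    score_full = formatC(res$score, format = "g", digits = 17),
    matched = res$matched, total = res$total,
    source = res$source, mtype = res$mtype, ph = sprintf("%.2f", res$ph),
    solvent = res$solvent, frequency = res$frequency,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
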