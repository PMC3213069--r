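## broom-style verbs: tidy() flattens a result to a plain tibble, glance()
## gives a one-row summary.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy.mh_result
#' @method tidy search_config
#' @export
tidy.search_config <- function(x, ...) {
  tibble(method = x$method, eta = x$eta, r = x$r, tolerance = x$tolerance,
         max_results = x$max_results, score_fn = x$score_fn,
         experimental_drift = x$experimental_drift)
}

#' Tidy and summarise search results
#'
#' `tidy()` returns the ranked hits as a plain tibble (the list-column of
#' matched coordinates collapsed to a comma-separated string); `glance()`
#' returns a one-row summary of the run.
#'
#' @param x An `mh_result` from [search_mh1()], [search_mh2()] or
#'   [search_mh3()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mh_result
#' @export
tidy.mh_result <- function(x, ...) {
  out <- as_tibble(x)
  out$matched_coords <- vapply(out$matched_coords,
                               function(v) paste(format_ppm(v), collapse = ","),
                               character(1))
  out
}

#' @rdname tidy.mh_result
#' @method glance mh_result
#' @export
glance.mh_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    method = cfg$method, r = cfg$r, tolerance = cfg$tolerance,
    k = attr(x, "k"), n_sample_peaks = attr(x, "n_sample_peaks"),
    n_hits = nrow(x),
    top_score = if (nrow(x)) x$score[1] else NA_real_
  )
}

#' @rdname tidy.mh_result
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.mh_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
         optimal_accuracy = x$optimal_accuracy,
         max_cutoff = max(x$points$cutoff))
}

#' @rdname tidy.mh_result
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble(cutoff = x$cutoff, tp = x$tp, fp = x$fp,
                          fn = x$fn, tn = x$tn, k = x$k),
                   confusion_stats(x))
}
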