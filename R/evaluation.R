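## Evaluation against a known mixture: confusion matrices over ranked-list
## cut-offs, sensitivity/specificity/accuracy, ROC curves with trapezoidal
## AUC and accuracy-optimal cut-off selection, and the ranking metrics
## (% identified within a list cap, average rank of the identified).

#' Confusion matrix at a ranked-list cut-off
#'
#' A prediction set is the first `cutoff` entries of the ranked results; a
#' member of the true mixture inside it is a true positive.  True negatives
#' are counted against the library size: `tn = k - tp - fp - fn`.
#'
#' @param ranked Character vector of metabolite ids in rank order (or an
#'   `mh_result`).
#' @param truth A `mixture_truth` or character vector of true member ids.
#' @param cutoff Cut-off `N >= 1`.  When `N` exceeds the ranked list's
#'   length, the whole list is used.
#' @param k Library size.
#' @return A `confusion_matrix` list: `tp`, `fp`, `fn`, `tn`, `k`, `cutoff`.
#' @examples
#' confusion_at_cutoff(c("A", "C", "B"), c("A", "B"), cutoff = 2, k = 10)
#' @export
confusion_at_cutoff <- function(ranked, truth, cutoff, k) {
  ranked <- ranked_ids(ranked)
  truth <- truth_ids(truth)
  if (!is.numeric(cutoff) || cutoff < 1) {
    abort("`cutoff` must be >= 1.", class = "specmatch_config_error")
  }
  top <- head(ranked, cutoff)
  tp <- sum(top %in% truth)
  fp <- length(top) - tp
  fn <- length(truth) - tp
  tn <- k - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, k = k, cutoff = cutoff),
            class = "confusion_matrix")
}

ranked_ids <- function(x) {
  if (inherits(x, "mh_result")) x$metabolite_id else as.character(x)
}

truth_ids <- function(x) {
  if (inherits(x, "mixture_truth")) x$member_ids else as.character(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("# Confusion matrix at cut-off %d (library size %d)\n",
              x$cutoff, x$k))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/k`.  A statistic with a zero denominator is
#' undefined and reported as `NA` rather than raising an error.
#'
#' @param cm A [confusion_at_cutoff()] result.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_stats <- function(cm) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    accuracy = safe_div(cm$tp + cm$tn, cm$k)
  )
}

#' ROC curve, AUC and accuracy-optimal cut-off
#'
#' Sweeps the cut-off `N = 1 ... max_cutoff`, records (false-positive rate,
#' sensitivity) at each, and integrates the curve by the trapezoidal rule
#' with the curve anchored at (0, 0) and extended horizontally to (1, last
#' sensitivity).  The optimal cut-off is the `N` maximising accuracy, ties
#' resolved toward the smallest `N`.
#'
#' @inheritParams confusion_at_cutoff
#' @param max_cutoff Largest cut-off to sweep (default `k`).
#' @return A `roc_result` list: `points` (tibble `cutoff`, `fpr`,
#'   `sensitivity`, `specificity`, `accuracy`), `auc`, `optimal_cutoff`,
#'   `optimal_accuracy`.
#' @export
roc_curve <- function(ranked, truth, k, max_cutoff = k) {
  ranked <- ranked_ids(ranked)
  truth <- truth_ids(truth)
  if (!length(truth)) {
    abort("`truth` is empty; ROC/AUC undefined.",
          class = "specmatch_config_error")
  }
  if (max_cutoff < 1) {
    abort("`max_cutoff` must be >= 1.", class = "specmatch_config_error")
  }
  pts <- purrr::map_dfr(seq_len(max_cutoff), function(N) {
    cm <- confusion_at_cutoff(ranked, truth, N, k)
    st <- confusion_stats(cm)
    tibble(cutoff = N, fpr = 1 - st$specificity,
           sensitivity = st$sensitivity, specificity = st$specificity,
           accuracy = st$accuracy)
  })
  auc <- trapezoid_auc(pts$fpr, pts$sensitivity)
  best <- which.max(pts$accuracy)  # which.max takes the first (smallest N) tie
  structure(list(points = pts, auc = auc,
                 optimal_cutoff = pts$cutoff[best],
                 optimal_accuracy = pts$accuracy[best]),
            class = "roc_result")
}

## trapezoid over (x, y) anchored at (0,0) and extended to (1, last y);
## duplicate x (vertical segments) contribute zero area, as they should
trapezoid_auc <- function(x, y) {
  x <- c(0, x, 1)
  y <- c(0, y, y[length(y)])
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("# ROC over cut-offs 1..%d: AUC %.3f; optimal cut-off %d (accuracy %.3f)\n",
              max(x$points$cutoff), x$auc, x$optimal_cutoff, x$optimal_accuracy))
  invisible(x)
}

#' Ranking metrics for an identified mixture
#'
#' Two summaries of how well a ranked list recovers a known mixture: the
#' percentage of true members appearing within the first `cap` results, and
#' the average rank of those that do.  When none are identified the average
#' rank is reported as `cap` (the list-cap convention: a miss is "as bad as
#' the bottom of the reported list").
#'
#' @inheritParams confusion_at_cutoff
#' @param cap List cap (default 100).
#' @return A one-row tibble: `n_truth`, `n_identified`, `pct_identified`,
#'   `avg_rank`.
#' @examples
#' rank_metrics(c("A", "x", "B"), c("A", "B"))  # 100%, mean rank 2
#' @export
rank_metrics <- function(ranked, truth, cap = 100) {
  ranked <- ranked_ids(ranked)
  truth <- truth_ids(truth)
  if (!length(truth)) {
    abort("`truth` is empty; ranking metrics undefined.",
          class = "specmatch_config_error")
  }
  if (cap < 1) abort("`cap` must be >= 1.", class = "specmatch_config_error")
  top <- head(ranked, cap)
  pos <- match(truth, top)
  hit <- !is.na(pos)
  tibble(
    n_truth = length(truth),
    n_identified = sum(hit),
    pct_identified = 100 * sum(hit) / length(truth),
    avg_rank = if (any(hit)) mean(pos[hit]) else as.numeric(cap)
  )
}
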