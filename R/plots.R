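## ggplot2 views of the result types.  autoplot() methods return ggplot
## objects; nothing is drawn until printed.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_segment geom_abline geom_col labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot methods for specmatch results
#'
#' * `autoplot.raw_spectrum()`: the intensity trace on the conventional
#'   reversed ppm axis.
#' * `autoplot.peak_list()`: picked/supplied peaks as vertical segments.
#' * `autoplot.mh_result()`: score against rank for the reported hits.
#' * `autoplot.roc_result()`: the ROC curve with the chance diagonal.
#' * `autoplot.recovery_experiment()`: mean recovery against mixture size.
#' * `autoplot.noise_experiment()`: mean identification against noise level,
#'   faceted by noise channel.
#' * `autoplot.scoring_comparison()`: top-1 accuracy under each scoring
#'   function.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-specmatch
NULL

#' @rdname autoplot-specmatch
#' @method autoplot raw_spectrum
#' @export
autoplot.raw_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$ppm, y = .data$intensity)) +
    geom_line() +
    ggplot2::scale_x_reverse() +
    labs(x = "chemical shift (ppm)", y = "intensity") +
    theme_minimal()
}

#' @rdname autoplot-specmatch
#' @method autoplot peak_list
#' @export
autoplot.peak_list <- function(object, ...) {
  ggplot(object, aes(x = .data$ppm, xend = .data$ppm, y = 0,
                     yend = .data$height)) +
    geom_segment() +
    ggplot2::scale_x_reverse() +
    labs(x = "chemical shift (ppm)", y = "height") +
    theme_minimal()
}

#' @rdname autoplot-specmatch
#' @method autoplot mh_result
#' @export
autoplot.mh_result <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$rank, y = .data$score)) +
    geom_point() +
    geom_line() +
    labs(x = "rank", y = "significance score") +
    theme_minimal()
}

#' @rdname autoplot-specmatch
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_step() +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "false positive rate (1 - specificity)", y = "sensitivity",
         subtitle = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' @rdname autoplot-specmatch
#' @method autoplot recovery_experiment
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("all_pct", "topn_pct"),
                              names_to = "scope", values_to = "pct")
  long$scope <- ifelse(long$scope == "all_pct", "ALL", "TOPN")
  ggplot(long, aes(x = .data$n, y = .data$pct, colour = .data$method,
                   linetype = .data$scope)) +
    geom_line() +
    geom_point() +
    labs(x = "metabolites in mixture (n)", y = "% correctly identified") +
    theme_minimal()
}

#' @rdname autoplot-specmatch
#' @method autoplot noise_experiment
#' @export
autoplot.noise_experiment <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$level, y = .data$mean_pct, colour = .data$method)) +
    geom_line() +
    geom_point() +
    facet_wrap(~noise, scales = "free_x") +
    labs(x = "noise level (fraction removed / ppm shift)",
         y = "% correctly identified") +
    theme_minimal()
}

#' @rdname autoplot-specmatch
#' @method autoplot scoring_comparison
#' @export
autoplot.scoring_comparison <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$score_fn, y = .data$top1_pct)) +
    geom_col(width = 0.5) +
    labs(x = "scoring function", y = "top-1 identification %") +
    theme_minimal()
}
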