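#' Calibration and sensitivity plots for a benchmark run
#'
#' Calibration: false positive rate versus significance level, per method;
#' a calibrated test stays on or below the diagonal. Sensitivity: true
#' positive rate versus significance level.
#'
#' @param object an `altex_benchmark` tibble from [run_benchmark()].
#' @param alphas significance grid passed to [benchmark_curves()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.altex_benchmark <- function(object, alphas = seq(0.01, 0.5, by = 0.01),
                                     ...) {
  curves <- benchmark_curves(object, alphas)
  long <- tidyr::pivot_longer(curves, c("fpr", "tpr"),
                              names_to = "metric", values_to = "rate")
  long$metric <- factor(long$metric, c("fpr", "tpr"),
                        c("calibration (FPR)", "sensitivity (TPR)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha, y = .data$rate,
                                     colour = .data$method,
                                     linetype = .data$side)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_equal(xlim = c(0, max(alphas)), ylim = c(0, 1)) +
    ggplot2::labs(x = "significance level", y = "rate",
                  colour = "background", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Observed versus expected alteration margins of a background matrix
#'
#' Expected per-tumor alteration counts (column sums of the probability
#' matrix) against observed per-tumor counts, and the same per gene. Under
#' the entropy background both panels sit on the identity line; under the
#' binomial background only the gene panel does.
#'
#' @param object a `background_matrix`.
#' @param x an [alteration_matrix()] aligned with `object`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.background_matrix <- function(object, x, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(margin = "per tumor", observed = colSums(unclass(x)),
                   expected = colSums(object$probs)),
    tibble::tibble(margin = "per gene", observed = rowSums(unclass(x)),
                   expected = rowSums(object$probs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$expected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~margin, scales = "free") +
    ggplot2::labs(title = paste(object$method, "background"),
                  x = "observed alterations", y = "expected alterations") +
    ggplot2::theme_minimal()
}

#' Histogram of test p-values
#'
#' Quick diagnostic for calibration: null p-values should look (sub)uniform,
#' p-values of planted positives should pile up near zero.
#'
#' @param results a tibble with a `p_value` column, e.g. from
#'   [test_all_pairs()] or [run_benchmark()].
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(results, bins = 20) {
  p <- ggplot2::ggplot(results, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "p-value", y = "count") +
    ggplot2::theme_minimal()
  if (all(c("method", "case") %in% names(results)))
    p <- p + ggplot2::facet_grid(case ~ method)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
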