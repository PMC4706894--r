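# ggplot2 views of the result types.

#' Plot classifier importances of a capacity
#'
#' Bar chart of the Shapley values, the per-classifier importance indices
#' that sum to the capacity's total mass.
#'
#' @param object A [capacity()].
#' @param labels Optional element labels (default `"x0"..`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capacity <- function(object, labels = NULL, ...) {
  v <- shapley_values(object)
  labels <- labels %||% paste0("x", seq_along(v) - 1L)
  df <- tibble::tibble(element = factor(labels, levels = labels), shapley = v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element, y = .data$shapley)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Shapley value (importance)") +
    ggplot2::theme_minimal()
}

#' Plot an abstention-threshold sweep
#'
#' Errors and abstentions (and correct decisions) against the abstention
#' threshold: raising the threshold trades misclassifications for
#' abstentions, so the error curve is non-increasing and the abstention
#' curve non-decreasing.
#'
#' @param object A [threshold_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("correct", "errors", "abstentions"),
                              names_to = "outcome", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$count,
                                     colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "abstention threshold", y = "decisions", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion table with abstentions
#'
#' @param object A [confusion_with_abstention()] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_abstention <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "truth") |>
    tidyr::pivot_longer(-"truth", names_to = "decision", values_to = "count")
  df$decision <- factor(df$decision, levels = colnames(object))
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decision, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "decision", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot percentage improvements over base classifiers
#'
#' @param benchmark A table shaped like [speller_benchmark()].
#' @return A ggplot object faceted by metric and reference.
#' @export
plot_improvement <- function(benchmark = speller_benchmark()) {
  long <- fusion_improvement(benchmark) |>
    tidyr::pivot_longer(c("vs_average", "vs_best"),
                        names_to = "reference", values_to = "improvement")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subject, y = .data$improvement)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$metric), ggplot2::vars(.data$reference)) +
    ggplot2::labs(x = "subject", y = "% improvement of the fused framework") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
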