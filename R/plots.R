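## Thin plotting layer over the analysis outputs (ggplot2).

#' Accuracy versus number of classes
#' @param trace An `elimination_trace`.
#' @return A ggplot object.
#' @export
plot_elimination <- function(trace) {
  df <- as.data.frame(trace)
  ggplot2::ggplot(df, ggplot2::aes(x = n_classes, y = 100 * accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Number of classes", y = "Test accuracy (%)",
                  title = "Backward class elimination") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#' @param cm An `nb_confusion`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(cm$counts))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = true,
                                   fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = count), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Accuracy %.1f%%", 100 * cm$accuracy)) +
    ggplot2::theme_minimal()
}

#' Histogram of predicted classes
#' @param histogram Named counts (from [predict_reader()] or
#'   [evaluate_mixture()]).
#' @return A ggplot object.
#' @export
plot_prediction_histogram <- function(histogram) {
  df <- data.frame(class = factor(names(histogram), levels = names(histogram)),
                   count = as.numeric(histogram))
  ggplot2::ggplot(df, ggplot2::aes(x = class, y = count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "Predicted class", y = "Count") +
    ggplot2::theme_minimal()
}

#' Scatter of PCA fingerprint scores
#' @param pca A `pca_fingerprint`.
#' @param components Two component indices to plot.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, components = c(1L, 2L)) {
  df <- data.frame(x = pca$scores[, components[1]],
                   y = pca$scores[, components[2]])
  if (!is.null(pca$label)) df$label <- factor(pca$label)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  pca$explained_variance[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  pca$explained_variance[components[2]])) +
    ggplot2::theme_minimal()
  if (!is.null(pca$label)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = label),
                            size = 0.6, alpha = 0.6)
  } else {
    p + ggplot2::geom_point(size = 0.6, alpha = 0.6)
  }
}
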