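# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.confusion_matrix <- function(object, percentages = TRUE, ...) {
  m <- if (percentages) confusion_percentages(object) else unclass(object)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("reference", "prediction", "value")
  df$reference <- factor(df$reference, levels = rev(rownames(m)))
  df$prediction <- factor(df$prediction, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$reference,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#08306b",
      name = if (percentages) "% of class" else "count") +
    ggplot2::labs(x = "Prediction", y = "Reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.shape_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (object$n_retained < 2) {
    abort("need at least 2 retained components to plot scores")
  }
  pct <- 100 * object$eigenvalues / sum(object$eigenvalues)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$shape_pc_1, y = .data$shape_pc_2))
  if (!is.null(colour_by) && colour_by %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                                 alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::labs(x = sprintf("Shape PC1 (%.1f%%)", pct[1]),
                  y = sprintf("Shape PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gpa <- function(object, ...) {
  ggplot2::ggplot(object$aligned, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.8) +
    ggplot2::geom_point(data = object$mean_shape, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Procrustes-superimposed configurations (consensus in red)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-cultivar prediction rates per method
#'
#' @param summary a [per_cultivar_summary()] tibble.
#' @return a ggplot object.
#' @export
plot_cultivar_summary <- function(summary) {
  long <- tidyr::pivot_longer(summary, -"cultivar",
                              names_to = "method", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cultivar, y = .data$rate,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Fraction of test fruit correct") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
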