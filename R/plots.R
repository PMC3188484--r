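# ggplot2 visualizations for the package's result types.

#' @export
autoplot.binary_image <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object)) - 1L,
                           x = seq_len(ncol(object)) - 1L)
  df$on <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$on)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @export
autoplot.orientation_field <- function(object, ...) {
  mx <- apply(unclass(object), c(1, 2), max)
  df <- tidyr::expand_grid(y = seq_len(nrow(mx)) - 1L,
                           x = seq_len(ncol(mx)) - 1L)
  df$activity <- as.vector(mx)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "max activity") +
    ggplot2::theme_void()
}

#' @export
autoplot.lateral_kernel <- function(object, ...) {
  D <- dim(object$canonical)[1]
  R <- (D - 1) / 2
  n_rel <- dim(object$canonical)[3]
  df <- tidyr::expand_grid(theta_rel = seq_len(n_rel) - 1L,
                           dx = seq(-R, R), dy = seq(-R, R))
  df <- df[order(df$theta_rel, df$dx, df$dy), ]
  df$value <- as.vector(object$canonical)
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$dx, .data$dy,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~theta_rel, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$kind, "kernel (canonical)"),
                  fill = "K")
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc")))
}

#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  curve <- tibble::tibble(x = grid, auc = predict(object, grid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey60") +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iterations / SOA", y = "AUC",
                  subtitle = sprintf("tau = %.3g, asymptote = %.3f",
                                     object$tau, object$asymptote))
}

#' Plot AUC against iterations per complexity
#'
#' @param results tibble from [evaluate_kernel()] (optionally with a
#'   `strength` column, mapped to line width).
#' @return a ggplot.
#' @export
plot_evaluation <- function(results) {
  p <- ggplot2::ggplot(
    results,
    ggplot2::aes(.data$iteration, .data$auc,
                 color = factor(.data$n_freq),
                 group = if ("strength" %in% names(results)) {
                   interaction(results$n_freq, results$strength)
                 } else {
                   factor(results$n_freq)
                 })
  ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pc - .data$pc_se,
                                        ymax = .data$pc + .data$pc_se),
                           width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = "lateral-interaction iterations", y = "AUC",
                  color = "radial\nfrequencies") +
    ggplot2::ylim(0.25, 1)
  if ("strength" %in% names(results)) {
    p <- p + ggplot2::aes(linewidth = .data$strength) +
      ggplot2::scale_linewidth(range = c(0.3, 1.5))
  }
  p
}
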