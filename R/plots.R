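#' Plot autodecoder training history
#'
#' @param object an `sdf_autodecoder`.
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sdf_autodecoder <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_clamped_error)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean per-row clamped |error|",
                  title = "SDF autodecoder training") +
    ggplot2::theme_minimal()
}

#' Plot a per-axis phylogenetic signal profile
#'
#' @param object a `signal_profile` tibble.
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.signal_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = as.integer(.data$axis), y = .data$K)) +
    ggplot2::geom_col(fill = "coral", width = 0.8) +
    ggplot2::labs(x = "axis", y = "Blomberg's K",
                  title = "Phylogenetic signal by axis") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object an `eval_report`.
#' @param ... ignored.
#' @return a ggplot heat map (rows = truth, columns = prediction), tile
#'   fill proportional to the row-normalized rate.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::mutate(df,
    rate = .data$n / pmax(stats::ave(.data$n, .data$truth, FUN = sum), 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy %.2f, balanced accuracy %.2f",
                                  object$accuracy, object$balanced_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a 2-d latent embedding
#'
#' @param object an `embed2d` matrix.
#' @param labels optional point labels (e.g. trophic niche) for coloring.
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.embed2d <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(dim1 = object[, 1], dim2 = object[, 2])
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::labs(title = paste(attr(object, "method"), "embedding")) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$label), alpha = 0.8)
}
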