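# ggplot2 visualisations for the result objects.

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("actual", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      title = sprintf("%s: accuracy %.3f", object$model, object$accuracy),
      x = "predicted", y = "actual"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @method autoplot benchmark_tbl
#' @export
autoplot.benchmark_tbl <- function(object, metric = "accuracy", ...) {
  stopifnot(metric %in% names(object))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data[[metric]],
                                       fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric, fill = "features") +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(
      title = sprintf("%s: %d-fold CV, mean %.3f +/- %.3f",
                      object$model, object$n_folds, object$mean, object$sd),
      x = "fold", y = "accuracy"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot probfs_tbl
#' @export
autoplot.probfs_tbl <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$P2, y = .data$P4)) +
    ggplot2::labs(
      title = paste0("ProBFS (", attr(object, "mode"), " mode)"),
      x = "SVM probability of second class (P2)",
      y = "LR probability of second class (P4)"
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.4)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.4)
  }
}
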