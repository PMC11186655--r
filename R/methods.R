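#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble (`class`, `precision`, `recall`, `f1`,
#'   `support`).
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with macro `precision`, `recall`, `f1`, `accuracy`, `n`,
#'   `labeled_ratio`, `variant`.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall, f1 = x$f1,
                 accuracy = x$accuracy, n = x$n,
                 labeled_ratio = x$labeled_ratio, variant = x$variant)
}

#' @rdname tidy.metrics_report
#' @method tidy contrastive_fit
#' @export
tidy.contrastive_fit <- function(x, ...) x$history

#' @rdname glance.metrics_report
#' @method glance contrastive_fit
#' @export
glance.contrastive_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_loss = if (nrow(x$history)) {
                   x$history$mean_loss[nrow(x$history)]
                 } else NA_real_)
}

#' @rdname tidy.metrics_report
#' @method tidy finetune_fit
#' @export
tidy.finetune_fit <- function(x, ...) x$history

#' @rdname glance.metrics_report
#' @method glance finetune_fit
#' @export
glance.finetune_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_loss = if (nrow(h)) h$mean_loss[nrow(h)] else NA_real_,
                 final_train_accuracy = if (nrow(h)) {
                   h$train_accuracy[nrow(h)]
                 } else NA_real_)
}

#' Plot a confusion matrix heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.3f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a training loss trajectory
#'
#' @param object A `contrastive_fit` or `finetune_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contrastive_fit
#' @export
autoplot.contrastive_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "mean NT-Xent loss", title = "Contrastive pretraining") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.contrastive_fit
#' @method autoplot finetune_fit
#' @export
autoplot.finetune_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Fine-tuning") +
    ggplot2::theme_minimal()
}

#' Plot a labeled-ratio sweep or ablation table
#'
#' @param results Tibble from [run_experiment()], [ratio_sweep()] or
#'   [ablation_run()].
#' @return A ggplot object: mean accuracy (over seeds) against labeled
#'   ratio, one line per variant.
#' @export
plot_experiment <- function(results) {
  agg <- dplyr::summarise(
    dplyr::group_by(results, .data$labeled_ratio, .data$variant),
    accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$labeled_ratio,
                                    y = .data$accuracy,
                                    colour = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "labeled ratio", y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @keywords internal
NULL
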