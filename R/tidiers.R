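# broom-style tidiers and plots for fitted objects.

#' Tidy a training run
#'
#' @param x An `icg_fit` from [train()].
#' @param ... Unused.
#' @return The per-epoch history as a tibble: `epoch`, `train_loss`,
#'   `train_acc`, `monitor_loss`, `monitor_acc`.
#' @exportS3Method generics::tidy
tidy.icg_fit <- function(x, ...) as_tibble(x$history)

#' @rdname tidy.icg_fit
#' @return `glance()`: a one-row tibble with `stopped_epoch`, `stop_reason`,
#'   the final losses/accuracies and the parameter count.
#' @exportS3Method generics::glance
glance.icg_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(stopped_epoch = x$stopped_epoch, stop_reason = x$stop_reason,
         train_loss = last$train_loss, train_acc = last$train_acc,
         monitor_loss = last$monitor_loss, monitor_acc = last$monitor_acc,
         n_parameters = count_parameters(x$model$spec))
}

#' @export
print.icg_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<icg_fit> stopped after epoch %d (%s)\n", g$stopped_epoch,
              g$stop_reason))
  cat(sprintf("  final: train loss %.4f / acc %.4f, monitor loss %.4f / acc %.4f\n",
              g$train_loss, g$train_acc, g$monitor_loss, g$monitor_acc))
  invisible(x)
}

#' Learning curves of a training run
#'
#' Accuracy and loss of the training and monitor cohorts per epoch, the
#' analogue of the study's learning-curve figure.
#'
#' @param object An `icg_fit`.
#' @param ... Unused.
#' @return A ggplot object with one panel for loss and one for accuracy.
#' @exportS3Method ggplot2::autoplot
autoplot.icg_fit <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = c("set", "metric"),
                              names_sep = "_", values_to = "value")
  long$metric <- ifelse(long$metric == "acc", "accuracy", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.icg_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$metrics[c("accuracy", "sensitivity", "specificity")],
    dplyr::everything(), names_to = "metric", values_to = "value")
}

#' @exportS3Method generics::glance
glance.icg_eval <- function(x, ...) x$metrics

#' @exportS3Method generics::tidy
tidy.icg_replication <- function(x, ...) as_tibble(x$replicates)

#' @exportS3Method generics::glance
glance.icg_replication <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::mutate(wide, n_replicates = x$n_replicates)
}

#' @exportS3Method generics::tidy
tidy.icg_sweep <- function(x, ...) as_tibble(x)

#' Export a training history as CSV
#'
#' @param fit An `icg_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  stopifnot(inherits(fit, "icg_fit"))
  readr::write_csv(tidy(fit), path)
  invisible(path)
}
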