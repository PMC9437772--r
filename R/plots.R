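#' Plot a realignment trace
#'
#' Translations (mm) and rotations (degrees) across time, one panel each,
#' the standard motion QC figure.
#'
#' @param object a `realignment_trace`.
#' @param ... ignored.
#' @export
autoplot.realignment_trace <- function(object, ...) {
  long <- tidy.realignment_trace(object) |>
    dplyr::mutate(
      kind = ifelse(.data$parameter %in% c("tx", "ty", "tz"),
                    "translation (mm)", "rotation (deg)"),
      value = ifelse(.data$parameter %in% c("tx", "ty", "tz"),
                     .data$value, .data$value * 180 / pi))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value,
                                     colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL, title = "Rigid realignment parameters") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training loss and validation Dice against the batch counter.
#'
#' @param object a `unet_fit`.
#' @param ... ignored.
#' @export
autoplot.unet_fit <- function(object, ...) {
  long <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_dice"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$batch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "batch", y = NULL, title = "U-Net training history") +
    ggplot2::theme_minimal()
}

#' Plot a censoring-threshold sweep
#'
#' Minutes of data retained per FD threshold for one or more subjects.
#'
#' @param sweep a [fd_sweep()] tibble, optionally with a `subject` column.
#' @export
plot_fd_sweep <- function(sweep) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold_mm,
                                           y = .data$minutes_retained))
  p <- if ("subject" %in% names(sweep))
    p + ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.5)
  else p + ggplot2::geom_line() + ggplot2::geom_point()
  p + ggplot2::labs(x = "FD censoring threshold (mm)",
                    y = "minutes retained",
                    title = "Data retained across censoring thresholds") +
    ggplot2::theme_minimal()
}

#' Plot per-volume segmentation metrics
#'
#' @param metrics a tibble of [compute_metrics()] rows.
#' @export
plot_metrics <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(c("dice", "jaccard", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Mask agreement with reference") +
    ggplot2::theme_minimal()
}
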