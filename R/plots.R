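#' Plot a hypnogram
#'
#' Classic stair-step display: time on the horizontal axis, the three
#' vigilance stages stacked vertically (WAKE on top, REM at the bottom,
#' mirroring how sleep researchers read depth).
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypnogram <- function(object, ...) {
  epoch_length <- attr(object, "epoch_length") %||% 20
  df <- tibble(hours = object$epoch * epoch_length / 3600,
               level = 4 - as.integer(object$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$level)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = 3:1, labels = STAGE_LEVELS,
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = attr(object, "record_id")) +
    ggplot2::theme_minimal()
}

#' Plot scoring certainties
#'
#' Per-epoch softmax certainties of the three stages plus the assigned
#' label, useful for eyeballing where the rescoring pass will trigger.
#'
#' @param object A prediction tibble from [predict.sleep_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_prediction <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("epoch", "p_wake", "p_nrem", "p_rem")],
    -"epoch", names_to = "stage", values_to = "certainty")
  df$stage <- factor(df$stage, levels = c("p_wake", "p_nrem", "p_rem"),
                     labels = STAGE_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$certainty,
                                   colour = .data$stage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "epoch", y = "certainty") +
    ggplot2::theme_minimal()
}

#' Plot the training loss history
#'
#' @param model A trained `sleep_model`.
#' @return A ggplot object (loss per pass, one panel per training phase).
#' @export
plot_training_history <- function(model) {
  if (is.null(model$history)) abort("model has no training history")
  ggplot2::ggplot(model$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~phase, scales = "free") +
    ggplot2::labs(x = "pass", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}
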