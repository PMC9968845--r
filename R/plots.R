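#' Plot a time-frequency response
#'
#' Time-frequency power map (one facet per channel), the standard way to
#' eyeball mu-band ERD during imagery and the post-imagery beta rebound.
#' Baseline-correct first for a signed ERD/ERS map.
#'
#' @param object A `tf_response`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_response <- function(object, ...) {
  df <- expand.grid(
    channel = dimnames(object$power)[[1]],
    freq = object$freqs,
    time = object$times,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$power <- as.vector(object$power)
  fill_lab <- if (object$baseline_corrected) "power - baseline" else "power"
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(name = bquote(.(fill_lab) ~ (mu * V^2))) +
    ggplot2::geom_vline(xintercept = c(0, 4), linetype = "dashed",
                        colour = "white") +
    ggplot2::labs(
      x = "time relative to imagery onset (s)", y = "frequency (Hz)",
      title = sprintf("Time-frequency response (%s trials, n = %d)",
                      object$class, object$n_trials)
    )
}

#' Plot a transfer matrix
#'
#' Accuracy heat map of the cross-train/test matrix; the diagonal is the
#' within-session self-test.
#'
#' @param object A `cross_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$test, .data$train,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$accuracy)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "grey95",
                                 limits = c(0, 100), name = "accuracy (%)") +
    ggplot2::scale_y_discrete(limits = rev(object$sessions)) +
    ggplot2::labs(x = "test session", y = "training session")
}

#' Plot a 2-D CSP feature cloud
#'
#' Scatter of the first two CSP log band-power features coloured by class,
#' with class centres marked.
#'
#' @param object A `feature_set` with at least two feature columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_set <- function(object, ...) {
  df <- tibble(
    f1 = object$f1, f2 = object$f2,
    class = factor(object$label, levels = c(1, 2),
                   labels = c("left", "right"))
  )
  centres <- df |> dplyr::group_by(.data$class) |>
    dplyr::summarise(f1 = mean(.data$f1), f2 = mean(.data$f2),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = centres, shape = 4, size = 4,
                        stroke = 2) +
    ggplot2::labs(x = "log band power, filter 1",
                  y = "log band power, filter 2")
}

#' Plot strategy performance
#'
#' Mean accuracy per training-set selection strategy with per-target
#' points overlaid.
#'
#' @param report A `strategy_report` from [evaluate_strategies()].
#' @return A ggplot object.
#' @export
plot_strategies <- function(report) {
  means <- summarise_strategies(report)
  ggplot2::ggplot(report, ggplot2::aes(.data$strategy, .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.5, na.rm = TRUE,
                        position = ggplot2::position_jitter(width = 0.1,
                                                            height = 0)) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(y = .data$mean_accuracy),
                        colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = NULL, y = "accuracy (%)")
}
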