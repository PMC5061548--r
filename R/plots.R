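#' Plot a copy-number estimate
#'
#' Minimum, read-depth average (with its bootstrap CI) and maximum as a
#' dot-and-whisker summary.
#'
#' @param object A [estimate_copy_number()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.copy_number_estimate <- function(object, ...) {
  df <- tibble(
    method = factor(c("minimum\n(1:1 orthology)", "average\n(read depth)",
                      "maximum\n(reconciliation)"),
                    levels = c("minimum\n(1:1 orthology)",
                               "average\n(read depth)",
                               "maximum\n(reconciliation)")),
    value = c(object$minimum, object$average, object$maximum),
    lo = c(NA, object$ci[1], NA), hi = c(NA, object$ci[2], NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "copy number") +
    ggplot2::theme_minimal()
}

#' Plot copies-through-time against a body-size series
#'
#' The resampled, rescaled pair of series from a [correlate_series()]
#' result, on a time axis running toward the present.
#'
#' @param object A `trend_correlation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_correlation <- function(object, ...) {
  s <- object$series
  scale01 <- function(v) (v - min(v)) / (max(v) - min(v))
  df <- bind_rows(
    tibble(time = s$time, value = scale01(s$a), series = "copy number"),
    tibble(time = s$time, value = scale01(s$b), series = "body size"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_step(data = ~ filter(.x, .data$series == "copy number")) +
    ggplot2::geom_line(data = ~ filter(.x, .data$series == "body size")) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "time (MY before present)", y = "scaled value",
                  colour = NULL,
                  subtitle = sprintf("r = %.2f (circular-shift p = %.3g)",
                                     object$estimate, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated gene-copy trajectory
#'
#' @param copies A [copies_through_time()] tibble.
#' @return A ggplot step curve.
#' @export
plot_copies_through_time <- function(copies) {
  ggplot2::ggplot(copies, ggplot2::aes(x = .data$time, y = .data$copies)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "time (MY before present)", y = "gene copies") +
    ggplot2::theme_minimal()
}
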