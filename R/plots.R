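# ggplot2 views of the main result types.

#' @describeIn estimate_hurst Log-log lag-variance plot with the fitted
#'   scaling line; the slope is `2H`.
#' @param object A `hurst_fit`.
#' @export
autoplot.hurst_fit <- function(object, ...) {
  lv <- object$lag_table
  ggplot2::ggplot(lv, ggplot2::aes(x = log(.data$lag), y = log(.data$variance))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = expression(log(tau)), y = expression(log(Var(tau))),
      title = sprintf("H = %.3f  (slope = %.3f, r² = %.3f)",
                      object$H, object$slope, object$r_squared))
}

#' @describeIn scan_thresholds Mean degree against threshold, the curve used
#'   to match networks from different systems at a common mean degree.
#' @param object A `threshold_scan`.
#' @param ... Unused.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$mean_degree)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "threshold p", y = "mean degree ⟨k⟩")
}

#' @describeIn simulate_ising Magnetization trace of the recorded sweeps.
#' @param object An `ising_run`.
#' @param ... Unused.
#' @export
autoplot.ising_run <- function(object, ...) {
  ggplot2::ggplot(object$magnetization, ggplot2::aes(x = .data$step, y = .data$M)) +
    ggplot2::geom_line() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "sweep", y = "M",
                  title = sprintf("L = %d, T = %.2f", object$config$L,
                                  object$config$T))
}

#' Degree histogram on log-log axes
#'
#' Frequency of each degree value, log-log, the standard first look at a
#' possible heavy tail.
#'
#' @param degrees Integer degree sequence (e.g. [degree_sequence()]).
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  df <- tibble::tibble(degree = as.numeric(names(tab)),
                       count = as.numeric(tab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "frequency")
}

#' Write a degree histogram as delimited text
#'
#' Two-column `degree,count` text for external plotting.
#'
#' @param degrees Integer degree sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degree_histogram <- function(degrees, path) {
  tab <- table(factor(degrees, levels = 0:max(degrees)))
  df <- data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  df <- df[df$count > 0, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
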