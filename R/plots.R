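#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a corrected FRAP curve with its one-phase association fit
#'
#' @param object A `frap_curve` from [correct_trace()].
#' @param fit Optional `frap_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_curve <- function(object, fit = NULL, ...) {
  bf <- attr(object, "bleach_frame")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$time_s[bf], colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "Time (s)", y = "Normalized intensity") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    post <- object[object$phase == "post", ]
    xx <- post$time_s - post$time_s[1]
    pred <- tibble(time_s = post$time_s,
                   intensity = fit$y0 + (fit$plateau - fit$y0) * (1 - exp(-fit$k_per_s * xx)))
    p <- p + ggplot2::geom_line(data = pred, colour = "blue")
  }
  p
}

#' Plot an MSD curve on log-log axes with its power-law fit
#'
#' @param object Output of [msd()].
#' @param fit Optional `msd_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_s, y = .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    pred <- tibble(tau_s = object$tau_s,
                   msd_um2 = 4 * fit$d_app * object$tau_s^fit$alpha)
    p <- p + ggplot2::geom_line(data = pred, colour = "blue")
  }
  p
}

#' Per-cell event-engagement plot (median with interquartile range)
#'
#' @param engagement Output of [event_engagement()] with a `condition`
#'   column.
#' @return A ggplot.
#' @export
plot_engagement <- function(engagement) {
  summ <- summarize_engagement(engagement)
  ggplot2::ggplot(engagement,
                  ggplot2::aes(x = .data$condition, y = 100 * .data$engagement)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(x = .data$condition, y = 100 * .data$median,
                   ymin = 100 * .data$q25, ymax = 100 * .data$q75),
      colour = "red", inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "Chromocenters engaging in events (%)") +
    ggplot2::theme_minimal()
}

#' Quartile-fraction bar plot
#'
#' @param qb Output of [quartile_bin()].
#' @return A ggplot.
#' @export
plot_quartiles <- function(qb) {
  ggplot2::ggplot(qb$fractions,
                  ggplot2::aes(x = .data$quartile, y = .data$fraction,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Quartile (reference boundaries)", y = "Fraction") +
    ggplot2::theme_minimal()
}

#' Lifetime dot plot per region and condition
#'
#' @param lifetimes Tibble with `region_label`, `condition`, `tau_ns`.
#' @return A ggplot.
#' @export
plot_lifetimes <- function(lifetimes) {
  ggplot2::ggplot(lifetimes,
                  ggplot2::aes(x = .data$condition, y = .data$tau_ns)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::facet_wrap(~ .data$region_label) +
    ggplot2::labs(x = NULL, y = "Fluorescence lifetime (ns)") +
    ggplot2::theme_minimal()
}
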