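#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return One-row tibble of the fitted quantities.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    y0 = x$y0, plateau = x$plateau, k_per_s = x$k_per_s, t_half_s = x$t_half_s,
    mobile_fraction = x$mobile_fraction, immobile_fraction = x$immobile_fraction,
    first_post = x$first_post, pre_bleach = x$pre_bleach, converged = x$converged
  )
}

#' @rdname tidy.frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(rss = x$rss, n_post = x$n_post, converged = x$converged)
}

#' Tidy an MSD fit
#'
#' @param x An `msd_fit` from [fit_msd()].
#' @param ... Unused.
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble(d_app = x$d_app, alpha = x$alpha, velocity_um_s = x$velocity_um_s,
         d_directed = x$d_directed, velocity_net_um_s = x$velocity_net_um_s)
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble(r2 = x$r2, fit_lags = x$fit_lags, dropped_lags = x$dropped_lags)
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<frap_fit> NOT CONVERGED:", x$diagnostics %||% "", "\n")
    return(invisible(x))
  }
  cat(sprintf("<frap_fit> t1/2 = %.2f s (K = %.4f /s), mobile = %.1f%%, immobile = %.1f%%\n",
              x$t_half_s, x$k_per_s, 100 * x$mobile_fraction, 100 * x$immobile_fraction))
  invisible(x)
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> alpha = %.3f, D_app = %.3g um^2/s^alpha, v = %.3g um/s (r2 = %.3f)\n",
              x$alpha, x$d_app, x$velocity_um_s, x$r2))
  invisible(x)
}

#' @export
print.chromo_tracks <- function(x, ...) {
  cat(sprintf("<chromo_tracks> %d tracks, %d points, %d events (max_disp = %.2f um)\n",
              nrow(x$tracks), nrow(x$points), nrow(x$events), x$max_disp_um))
  invisible(x)
}
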