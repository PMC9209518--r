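#' Generate a synthetic FRAP trace with known ground truth
#'
#' Simulates per-frame intensities of a bleached-chromocenter ROI, an
#' unbleached control-chromocenter ROI and a background ROI. The noiseless
#' bleached-ROI signal follows a one-phase association after the bleach
#' pulse,
#' \deqn{I(t) = [Y_0 + (P - Y_0)(1 - e^{-K t})] \, e^{-\lambda_{acq} t_{abs}},}
#' where \eqn{t} is time since the bleach, \eqn{Y_0} the first post-bleach
#' level, \eqn{P = Y_0 + F_m (1 - Y_0)} the plateau implied by the mobile
#' fraction \eqn{F_m}, and \eqn{\lambda_{acq}} a monoexponential
#' acquisition-bleaching rate shared by all three ROIs (clocked on absolute
#' acquisition time \eqn{t_{abs}}). Pre-bleach frames sit at the pre-bleach
#' level times the same acquisition-bleaching envelope.
#'
#' @param preset A FRAP preset list (see [chromodyn_preset()]), or a preset
#'   name such as `"tale_ctrl"`.
#' @param seed Integer seed; identical `(preset, seed)` gives an identical
#'   trace.
#' @param noise_sd Override of the preset noise level (additive Gaussian,
#'   expressed as a fraction of the pre-bleach intensity).
#'
#' @return A tibble of class `frap_trace` with columns `frame`, `time_s`,
#'   `i_bleached`, `i_control`, `i_background`, an attribute `bleach_frame`
#'   (index of the first post-bleach frame, 1-based) and a `ground_truth`
#'   attribute holding the generative parameters.
#' @examples
#' tr <- make_frap_trace("tale_ctrl", seed = 1)
#' head(tr)
#' attr(tr, "ground_truth")$k_per_s
#' @export
make_frap_trace <- function(preset, seed = 1L, noise_sd = NULL) {
  if (is.character(preset)) preset <- chromodyn_preset("frap", preset)
  validate_frap_preset(preset)
  if (!is.null(noise_sd)) preset$noise_sd <- noise_sd

  n_pre <- preset$pre_bleach_frames
  n_post <- preset$n_frames - n_pre
  t_pre <- (seq_len(n_pre) - 1) * preset$frame_interval_s
  t0 <- t_pre[n_pre] + preset$frame_interval_s
  t_post <- t0 + (seq_len(n_post) - 1) * preset$post_interval_s
  time_s <- c(t_pre, t_post)

  pre_level <- 1000
  bg_level <- 100
  y0 <- preset$bleach_depth
  plateau <- y0 + preset$mobile_fraction * (1 - y0)
  x <- t_post - t_post[1]
  recovery <- y0 + (plateau - y0) * (1 - exp(-preset$k_per_s * x))

  # ROIs contain signal plus background, all under the shared
  # acquisition-bleaching envelope, so the background/control correction in
  # correct_trace() recovers the recovery model exactly
  env <- exp(-preset$acq_bleach_per_s * time_s)
  i_bleached <- (pre_level * c(rep(1, n_pre), recovery) + bg_level) * env
  i_control <- (pre_level + bg_level) * env
  i_background <- bg_level * env

  with_seed(seed, {
    s <- preset$noise_sd * pre_level
    i_bleached <- i_bleached + rnorm(length(time_s), sd = s)
    i_control <- i_control + rnorm(length(time_s), sd = s)
    i_background <- i_background + rnorm(length(time_s), sd = 0.2 * s)
  })

  out <- tibble(
    frame = seq_along(time_s),
    time_s = time_s,
    i_bleached = i_bleached,
    i_control = i_control,
    i_background = i_background
  )
  structure(
    out,
    class = c("frap_trace", class(out)),
    bleach_frame = n_pre + 1L,
    ground_truth = list(
      preset = preset$name %||% "custom",
      y0 = y0, plateau = plateau, k_per_s = preset$k_per_s,
      mobile_fraction = preset$mobile_fraction,
      acq_bleach_per_s = preset$acq_bleach_per_s,
      pre_level = pre_level, background = bg_level
    )
  )
}
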