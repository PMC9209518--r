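#' Generate a synthetic TCSPC photon-arrival histogram
#'
#' Counts are a multinomial draw of `n_photons` from a monoexponential decay
#' \eqn{e^{-t/\tau}} discretized over `n_bins` bins, optionally convolved
#' with an instrument response function, with repetition-period wraparound
#' (photons emitted after one laser period fold back into the observation
#' window; for a 40 MHz source the period is 25 ns).
#'
#' @param tau_ns True lifetime (> 0).
#' @param n_photons Photon count (>= 1).
#' @param irf Optional IRF kernel: numeric vector of length `n_bins`
#'   (normalized internally), or `NULL` for a delta IRF.
#' @param bin_width_ns Bin width; default `rep_period_ns / n_bins`.
#' @param n_bins Number of bins (default 256).
#' @param rep_period_ns Laser repetition period (default 25 ns).
#' @param seed Integer seed.
#' @param region_label Optional label stored on the histogram.
#'
#' @return A tibble of class `flim_histogram` with `bin_start_ns`,
#'   `bin_mid_ns`, `counts`; attributes `rep_period_ns`, `tau_ns` (truth),
#'   `region_label`.
#' @export
make_flim_histogram <- function(tau_ns, n_photons, irf = NULL,
                                bin_width_ns = NULL, n_bins = 256,
                                rep_period_ns = 25, seed = 1L,
                                region_label = NA_character_) {
  assert_finite_scalar(tau_ns, "tau_ns", positive = TRUE)
  if (!is.numeric(n_photons) || n_photons < 1) abort("`n_photons` must be >= 1.")
  bin_width_ns <- bin_width_ns %||% (rep_period_ns / n_bins)
  if (n_bins * bin_width_ns > rep_period_ns + 1e-9) {
    abort("Bins must fit within one repetition period.")
  }
  edges <- (0:n_bins) * bin_width_ns
  # folded exponential: sum_k exp(-(t + k T)/tau) has the same shape as
  # exp(-t/tau) on [0, T), so bin masses are proportional to the plain
  # exponential integral over each bin
  p <- exp(-edges[-length(edges)] / tau_ns) - exp(-edges[-1] / tau_ns)
  if (!is.null(irf)) {
    irf <- rep_len(irf, n_bins)
    irf <- irf / sum(irf)
    p <- circular_convolve(p, irf)
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  counts <- with_seed(seed, as.integer(rmultinom(1, size = round(n_photons), prob = p)))
  out <- tibble(
    bin_start_ns = edges[-length(edges)],
    bin_mid_ns = edges[-length(edges)] + bin_width_ns / 2,
    counts = counts
  )
  structure(out, class = c("flim_histogram", class(out)),
            rep_period_ns = rep_period_ns, tau_ns = tau_ns,
            region_label = region_label)
}

circular_convolve <- function(x, k) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n
}

#' Render a synthetic SiR-DNA intensity image with chromatin-region truth
#'
#' A nucleus with bright heterochromatin spots on a dimmer euchromatin
#' background, for exercising [build_two_level_mask()]; truth masks are
#' returned alongside.
#'
#' @param preset Nucleus preset list or name (default `"gfp_gapmer"`).
#' @param seed Integer seed.
#' @return A list with `intensity` (matrix), `nuclei` (label matrix),
#'   `truth_het` / `truth_eu` (logical masks), `pixel_size_um`.
#' @export
make_flim_image <- function(preset = "gfp_gapmer", seed = 1L) {
  nuc <- make_rna_foci_nucleus(preset, seed = seed)
  het <- nuc$truth$cc_labels > 0
  eu <- nuc$truth$nucleus_mask & !het
  list(intensity = nuc$dapi,
       nuclei = nuc$truth$nucleus_mask * 1L,
       truth_het = het, truth_eu = eu,
       pixel_size_um = nuc$pixel_size_um)
}
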