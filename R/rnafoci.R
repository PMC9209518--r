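#' Classify an RNA focus by its chromocenter overlap fractions
#'
#' Rules: *within* when >50% of the focus overlaps a single chromocenter;
#' *between* when the focus overlaps (each <50%, and in total at most 100%)
#' at least two chromocenters; *periphery* when it overlaps exactly one
#' chromocenter by <50%; *unassociated* when it touches none. Exactly 50% is
#' assigned to the sub-50% branch.
#'
#' @param fractions Numeric vector of overlap fractions (one per
#'   chromocenter; zeros allowed).
#' @return One of `"within"`, `"periphery"`, `"between"`, `"unassociated"`.
#' @examples
#' classify_overlap(c(0.8, 0))        # within
#' classify_overlap(c(0.3, 0.2))      # between
#' classify_overlap(c(0.3, 0))        # periphery
#' classify_overlap(numeric(0))       # unassociated
#' @export
classify_overlap <- function(fractions) {
  if (any(fractions < 0 | fractions > 1)) abort("Overlap fractions must lie in [0, 1].")
  if (sum(fractions) > 1 + 1e-9) abort("Overlap fractions must sum to <= 1.")
  pos <- fractions[fractions > 0]
  if (!length(pos)) return("unassociated")
  if (max(pos) > 0.5) return("within")
  if (length(pos) >= 2) return("between")
  "periphery"
}

#' Detect RNA-FISH foci inside nuclei
#'
#' Gaussian smoothing, thresholding and connected-component labelling,
#' restricted to the nucleus mask; components below `min_area` pixels are
#' removed.
#'
#' @param fish Numeric matrix (FISH channel, registered to the nucleus mask).
#' @param nuclei Nucleus label map or logical mask; must contain >= 1
#'   nucleus.
#' @param smoothing_sigma Gaussian sigma in pixels.
#' @param threshold Absolute threshold after smoothing.
#' @param min_area Minimum focus area (pixels).
#' @return Integer label matrix of detected foci.
#' @export
detect_rna_foci <- function(fish, nuclei, smoothing_sigma = 1, threshold,
                            min_area = 5) {
  if (is.logical(nuclei)) nuclei <- nuclei * 1L
  if (max(nuclei) == 0) abort("No nuclei in the label map; cannot detect RNA foci.")
  sm <- as.matrix(EBImage::gblur(EBImage::Image(fish), sigma = smoothing_sigma))
  mask <- (sm > threshold) & (nuclei > 0)
  filter_labels(label_mask(mask), min_area)
}

#' Classify all detected RNA foci against a chromocenter label map
#'
#' For each detected focus, computes its pixel-overlap fraction with every
#' chromocenter label and applies [classify_overlap()].
#'
#' @param foci Integer label matrix of RNA foci (see [detect_rna_foci()]).
#' @param chromocenters `chromo_labels` or a chromocenter label matrix.
#' @param pixel_size_um Pixel size, for the reported focus area.
#' @param nucleus_id Identifier carried through.
#' @return A tibble with `nucleus_id`, `focus_id`, `area_px`, `area_um2`,
#'   `max_overlap`, `n_contacts`, `class`.
#' @export
classify_foci <- function(foci, chromocenters, pixel_size_um = 1,
                          nucleus_id = 1L) {
  cc <- if (inherits(chromocenters, "chromo_labels")) chromocenters$chromocenters else chromocenters
  nf <- max(foci)
  if (nf == 0) return(tibble())
  purrr::map_dfr(seq_len(nf), function(l) {
    sel <- foci == l
    n_px <- sum(sel)
    labs <- cc[sel]
    fr <- as.numeric(table(factor(labs[labs > 0], levels = seq_len(max(cc, 1))))) / n_px
    tibble(
      nucleus_id = nucleus_id, focus_id = l,
      area_px = n_px, area_um2 = n_px * pixel_size_um^2,
      max_overlap = if (length(fr)) max(fr) else 0,
      n_contacts = sum(fr > 0),
      class = classify_overlap(fr)
    )
  })
}

#' Fraction of nuclei containing at least one RNA focus
#'
#' @param records Tibble with one row per nucleus and a column
#'   `n_foci` (or per-focus records with `nucleus_id`, in which case nuclei
#'   absent from the table are not counted -- pass `n_nuclei` to include
#'   them), plus an optional `condition` column.
#' @param n_nuclei Total nuclei per condition (named vector or scalar) when
#'   `records` only lists nuclei with foci.
#' @param conf_level Binomial confidence level (Wilson interval).
#' @return A tibble per condition: `n_nuclei`, `n_with_foci`, `proportion`,
#'   `ci_lo`, `ci_hi`.
#' @export
foci_prevalence <- function(records, n_nuclei = NULL, conf_level = 0.95) {
  if (!"condition" %in% names(records)) records$condition <- "all"
  per_cond <- if ("n_foci" %in% names(records)) {
    records |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(n = dplyr::n(), k = sum(.data$n_foci > 0), .groups = "drop")
  } else {
    counts <- records |>
      dplyr::distinct(.data$condition, .data$nucleus_id) |>
      dplyr::count(.data$condition, name = "k")
    if (is.null(n_nuclei)) abort("`n_nuclei` is required with per-focus records.")
    counts$n <- if (length(n_nuclei) > 1) unname(n_nuclei[counts$condition]) else n_nuclei
    counts
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_cond |>
    dplyr::mutate(
      proportion = .data$k / .data$n,
      ci_lo = (.data$proportion + z^2 / (2 * .data$n) -
                 z * sqrt(.data$proportion * (1 - .data$proportion) / .data$n +
                            z^2 / (4 * .data$n^2))) / (1 + z^2 / .data$n),
      ci_hi = (.data$proportion + z^2 / (2 * .data$n) +
                 z * sqrt(.data$proportion * (1 - .data$proportion) / .data$n +
                            z^2 / (4 * .data$n^2))) / (1 + z^2 / .data$n)
    ) |>
    dplyr::rename(n_nuclei = "n", n_with_foci = "k")
}
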