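#' Detect droplets in a well image
#'
#' Threshold + connected components + circularity filter
#' (\eqn{4\pi A / P^2 \ge} `min_circularity`); diameters are those of the
#' equivalent-area circle. Saturated images (>5% of pixels at the maximum)
#' are flagged but still processed.
#'
#' @param image Numeric matrix.
#' @param pixel_size_um Calibrated pixel size (required).
#' @param threshold Absolute intensity threshold; `NULL` = midpoint between
#'   the image median and maximum (invariant to intensity gain).
#' @param min_diameter_um Minimum droplet diameter (default 1).
#' @param min_circularity Circularity cutoff (default 0.6).
#' @return A tibble with `droplet_id`, `diameter_um`, `area_px`,
#'   `circularity`; attribute `saturated`.
#' @export
detect_droplets <- function(image, pixel_size_um, threshold = NULL,
                            min_diameter_um = 1, min_circularity = 0.6) {
  assert_finite_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  saturated <- mean(image == max(image)) > 0.05
  if (saturated) warn("Well image looks saturated; processing anyway.")
  if (is.null(threshold)) {
    threshold <- (median(image) + max(image)) / 2
  }
  lab <- label_mask(image > threshold)
  nl <- max(lab)
  empty <- tibble(droplet_id = integer(0), diameter_um = numeric(0),
                  area_px = numeric(0), circularity = numeric(0))
  rows <- if (nl == 0) empty else {
    feats <- EBImage::computeFeatures.shape(lab)
    area <- feats[, "s.area"]
    per <- pmax(feats[, "s.perimeter"], 1)
    circ <- pmin(4 * pi * area / per^2, 1.2)
    diam <- 2 * sqrt(area / pi) * pixel_size_um
    keep <- which(diam >= min_diameter_um & circ >= min_circularity)
    tibble(droplet_id = as.integer(keep), diameter_um = unname(diam[keep]),
           area_px = as.numeric(area[keep]), circularity = unname(circ[keep]))
  }
  attr(rows, "saturated") <- saturated
  rows
}

#' Quantify every well of a droplet plate
#'
#' @param plate A `droplet_plate` (see [make_droplet_plate()]) or a tibble
#'   with columns `rna_species`, `conc_uM` and an `image` list-column.
#' @param pixel_size_um Pixel size (taken from the plate object if present).
#' @param ... Passed to [detect_droplets()].
#' @return A tibble per well: `rna_species`, `conc_uM`, `droplet_count`,
#'   `mean_diameter_um`, `diameters_um` (list-column).
#' @export
quantify_plate <- function(plate, pixel_size_um = NULL, ...) {
  wells <- if (inherits(plate, "droplet_plate")) plate$wells else plate
  pixel_size_um <- pixel_size_um %||% plate$pixel_size_um
  purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    dr <- detect_droplets(wells$image[[i]], pixel_size_um, ...)
    tibble(
      rna_species = wells$rna_species[i], conc_uM = wells$conc_uM[i],
      droplet_count = nrow(dr),
      mean_diameter_um = if (nrow(dr)) mean(dr$diameter_um) else NA_real_,
      diameters_um = list(dr$diameter_um)
    )
  })
}

#' Call the critical concentration per RNA species
#'
#' A well has detectable droplets when its droplet count is at least
#' `min_count` (default 5); the critical concentration is the minimum tested
#' concentration with detection. Detection should be monotone along the
#' dilution series: wells where a non-detected concentration sits above a
#' detected one are flagged as QC failures.
#'
#' @param results Per-well tibble from [quantify_plate()] (columns
#'   `rna_species`, `conc_uM`, `droplet_count`).
#' @param min_count Minimum droplet count for "detectable droplets".
#' @return A tibble per species: `rna_species`, `critical_conc_uM` (`NA` when
#'   no droplets at any tested concentration), `n_tested`, `qc_pass`.
#' @export
call_critical_concentration <- function(results, min_count = 5) {
  if (!nrow(results)) abort("Empty results; need at least one well per species.")
  results |>
    dplyr::group_by(.data$rna_species) |>
    dplyr::arrange(dplyr::desc(.data$conc_uM), .by_group = TRUE) |>
    dplyr::summarise(
      critical_conc_uM = {
        detected <- .data$droplet_count >= min_count
        if (any(detected)) min(.data$conc_uM[detected]) else NA_real_
      },
      n_tested = dplyr::n(),
      qc_pass = {
        detected <- .data$droplet_count >= min_count
        # detection must form a contiguous top block of the series
        all(detected == (seq_along(detected) <= sum(detected)))
      },
      .groups = "drop"
    )
}

#' Compare RNA species across a plate
#'
#' Orders species by called critical concentration and summarizes droplet
#' diameters, with pairwise two-sided Mann-Whitney tests on the diameters of
#' wells at or above each species' critical concentration.
#'
#' @param results Per-well tibble from [quantify_plate()] with a
#'   `diameters_um` list-column.
#' @param min_count Passed to [call_critical_concentration()].
#' @return A list with `critical` (ordered tibble), `sizes` (per-species
#'   diameter summaries) and `tests` (pairwise Mann-Whitney p-values).
#' @export
compare_species <- function(results, min_count = 5) {
  if (dplyr::n_distinct(results$rna_species) < 2) {
    abort("Need >= 2 RNA species to compare.")
  }
  crit <- call_critical_concentration(results, min_count) |>
    dplyr::arrange(.data$critical_conc_uM)
  diam <- results |>
    dplyr::left_join(crit, by = "rna_species") |>
    dplyr::filter(!is.na(.data$critical_conc_uM),
                  .data$conc_uM >= .data$critical_conc_uM) |>
    dplyr::select("rna_species", "diameters_um") |>
    tidyr::unnest("diameters_um") |>
    dplyr::rename(diameter_um = "diameters_um")
  sizes <- diam |>
    dplyr::group_by(.data$rna_species) |>
    dplyr::summarise(n_droplets = dplyr::n(),
                     mean_diameter_um = mean(.data$diameter_um),
                     median_diameter_um = median(.data$diameter_um),
                     .groups = "drop")
  sps <- unique(diam$rna_species)
  tests <- if (length(sps) >= 2) {
    purrr::map_dfr(utils::combn(sps, 2, simplify = FALSE), function(pr) {
      tibble(species1 = pr[1], species2 = pr[2],
             p_value = mw_test(diam$diameter_um[diam$rna_species == pr[1]],
                               diam$diameter_um[diam$rna_species == pr[2]]))
    })
  } else tibble()
  list(critical = crit, sizes = sizes, tests = tests)
}
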