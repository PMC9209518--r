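# place chromocenters inside a nucleus; a couple of near-touching pairs are
# guaranteed so that the "between" RNA localization class is geometrically
# feasible
place_chromocenters <- function(n_cc, r_cc_px, center_px, r_nuc_px, r_rna_px) {
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  n_pairs <- min(3L, n_cc %/% 2L)
  for (p in seq_len(n_pairs)) {
    for (try in 1:200) {
      r1 <- r_cc_px[length(radii) + 1]; r2 <- r_cc_px[length(radii) + 2]
      gap <- 1.2 * r_rna_px
      d <- r1 + r2 + gap
      rr <- (r_nuc_px - max(r1, r2) - d) * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      mid <- center_px + rr * c(sin(th), cos(th))
      phi <- runif(1, 0, 2 * pi)
      c1 <- mid + (d / 2) * c(sin(phi), cos(phi))
      c2 <- mid - (d / 2) * c(sin(phi), cos(phi))
      ok <- TRUE
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - c1[1])^2 + (centers[, 2] - c1[2])^2)
        dd2 <- sqrt((centers[, 1] - c2[1])^2 + (centers[, 2] - c2[2])^2)
        ok <- all(dd > radii + r1 + 3) && all(dd2 > radii + r2 + 3)
      }
      if (ok && sqrt(sum((c1 - center_px)^2)) + r1 < r_nuc_px - 1 &&
          sqrt(sum((c2 - center_px)^2)) + r2 < r_nuc_px - 1) {
        centers <- rbind(centers, c1, c2)
        radii <- c(radii, r1, r2)
        break
      }
    }
  }
  while (length(radii) < n_cc) {
    placed <- FALSE
    for (try in 1:200) {
      r1 <- r_cc_px[length(radii) + 1]
      rr <- (r_nuc_px - r1 - 2) * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      c1 <- center_px + rr * c(sin(th), cos(th))
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - c1[1])^2 + (centers[, 2] - c1[2])^2)
        # isolated foci stay > 2 RNA diameters clear of other chromocenters
        if (any(dd < radii + r1 + 4 * r_rna_px)) next
      }
      centers <- rbind(centers, c1)
      radii <- c(radii, r1)
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  list(centers = centers, radii = radii)
}

# fraction of an RNA-focus disk overlapping each chromocenter disk, computed
# on the pixel grid (the same convention the classifier uses)
overlap_fractions <- function(fy, fx, r_f, cc_centers, cc_radii) {
  n_px <- 0L
  counts <- numeric(nrow(cc_centers))
  yy <- seq(floor(fy - r_f), ceiling(fy + r_f))
  xx <- seq(floor(fx - r_f), ceiling(fx + r_f))
  for (y in yy) for (x in xx) {
    if ((y - fy)^2 + (x - fx)^2 > r_f^2) next
    n_px <- n_px + 1L
    d2 <- (cc_centers[, 1] - y)^2 + (cc_centers[, 2] - x)^2
    hit <- which(d2 <= cc_radii^2)
    if (length(hit)) counts[hit[1]] <- counts[hit[1]] + 1
  }
  if (n_px == 0) return(numeric(nrow(cc_centers)))
  counts / n_px
}

#' Generate a two-channel nucleus with RNA-FISH foci of known localization
#'
#' Renders a DAPI channel (nucleus + chromocenters) and a FISH channel (RNA
#' foci). Each RNA focus is assigned a localization class sampled from the
#' preset probabilities `(within, periphery, between)` and then placed so its
#' true pixel-overlap fractions satisfy that class rule with a safety margin:
#' *within* = >50% of the focus inside one chromocenter; *periphery* = <50%
#' overlap with exactly one chromocenter; *between* = <50% overlap with at
#' least two. Placement failures after bounded retries are skipped with a
#' warning and recorded in the truth table.
#'
#' @param preset Nucleus preset list or name (see
#'   [chromodyn_preset()]`("nucleus")`), e.g. `"gfp_gapmer"`.
#' @param seed Integer seed.
#' @param nucleus_id Identifier carried through outputs.
#'
#' @return A list of class `rna_nucleus` with elements `dapi`, `fish`,
#'   `h3k9me3`, `hp1a` (numeric matrices), `pixel_size_um`, `nucleus_id`,
#'   `truth` (list: `cc` tibble of chromocenter centers/radii (px), `foci`
#'   tibble with true class and overlap fractions, `cc_labels` integer truth
#'   label map, `nucleus_mask`).
#' @export
make_rna_foci_nucleus <- function(preset, seed = 1L, nucleus_id = 1L) {
  if (is.character(preset)) preset <- chromodyn_preset("nucleus", preset)
  validate_nucleus_preset(preset)
  ps <- preset$voxel_size_um
  shape <- unlist(preset$image_shape)
  ny <- shape[1]; nx <- shape[2]
  center <- c(ny, nx) / 2
  r_nuc <- 0.42 * min(ny, nx)
  r_rna <- preset$rna_radius_um / ps

  with_seed(derive_seed(seed, nucleus_id), {
    n_cc <- sample_spec(preset$n_chromocenters, 1, integer = TRUE)
    r_cc <- sample_spec(preset$cc_radius_um, n_cc + 4) / ps
    pl <- place_chromocenters(n_cc, r_cc, center, r_nuc, r_rna)
    cc_centers <- pl$centers
    cc_radii <- pl$radii
    n_cc <- length(cc_radii)

    # truth label map for the chromocenters
    cc_labels <- matrix(0L, ny, nx)
    for (l in seq_len(n_cc)) {
      m <- disk_mask(ny, nx, cc_centers[l, 1], cc_centers[l, 2], cc_radii[l])
      cc_labels[m] <- l
    }
    nucleus_mask <- disk_mask(ny, nx, center[1], center[2], r_nuc)

    n_foci <- sample_spec(preset$rna_foci_count, 1, integer = TRUE)
    probs <- unlist(preset$rna_class_probs)
    classes <- if (n_foci > 0) {
      sample(c("within", "periphery", "between"), n_foci, replace = TRUE, prob = probs)
    } else character(0)

    foci <- list()
    for (i in seq_len(n_foci)) {
      cls <- classes[i]
      placed <- FALSE
      for (try in 1:300) {
        if (cls == "within") {
          l <- sample.int(n_cc, 1)
          if (cc_radii[l] < 1.2 * r_rna) next
          rr <- max(cc_radii[l] - 1.3 * r_rna, 0) * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          p <- cc_centers[l, ] + rr * c(sin(th), cos(th))
        } else if (cls == "periphery") {
          l <- sample.int(n_cc, 1)
          th <- runif(1, 0, 2 * pi)
          d <- cc_radii[l] + runif(1, 0.1, 0.55) * r_rna
          p <- cc_centers[l, ] + d * c(sin(th), cos(th))
        } else {
          # between: target the midpoint of a near-touching chromocenter pair,
          # chosen at random among the feasible ones
          dmat <- as.matrix(stats::dist(cc_centers))
          gaps <- dmat - outer(cc_radii, cc_radii, "+")
          gaps[upper.tri(gaps, diag = TRUE)] <- Inf
          feas <- which(gaps <= 2.2 * r_rna, arr.ind = TRUE)
          if (!nrow(feas)) break  # no feasible pair
          pair <- feas[sample.int(nrow(feas), 1), ]
          a <- cc_centers[pair[1], ]; b <- cc_centers[pair[2], ]
          u <- (b - a) / sqrt(sum((b - a)^2))
          gap <- sqrt(sum((b - a)^2)) - cc_radii[pair[1]] - cc_radii[pair[2]]
          m0 <- a + u * (cc_radii[pair[1]] + gap / 2)
          p <- m0 + rnorm(2, sd = 0.15 * r_rna)
        }
        if (sqrt(sum((p - center)^2)) + r_rna > r_nuc - 1) next
        # keep foci apart so detection resolves them individually
        if (length(foci)) {
          placed_ok <- dplyr::bind_rows(foci)
          placed_ok <- placed_ok[!is.na(placed_ok$y_px), , drop = FALSE]
          if (nrow(placed_ok) &&
              min(sqrt((placed_ok$y_px - p[1])^2 + (placed_ok$x_px - p[2])^2)) < 3 * r_rna) {
            next
          }
        }
        fr <- overlap_fractions(p[1], p[2], r_rna, cc_centers, cc_radii)
        cls_true <- classify_overlap(fr)
        margin_ok <- switch(
          cls,
          within = fr[which.max(fr)] > 0.62,
          periphery = max(fr) < 0.42 && sum(fr > 0.05) == 1,
          between = sum(fr > 0.08) >= 2 && max(fr) < 0.42
        )
        if (cls_true == cls && margin_ok) {
          foci[[length(foci) + 1]] <- tibble(
            focus_id = length(foci) + 1L, class = cls,
            y_px = p[1], x_px = p[2], radius_px = r_rna,
            max_overlap = max(fr), n_contacts = sum(fr > 0)
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warn(sprintf("RNA focus %d (class '%s') could not be placed; skipped.", i, cls))
        foci[[length(foci) + 1]] <- tibble(
          focus_id = NA_integer_, class = cls, y_px = NA_real_, x_px = NA_real_,
          radius_px = r_rna, max_overlap = NA_real_, n_contacts = NA_integer_
        )
      }
    }
    foci <- if (length(foci)) dplyr::bind_rows(foci) else
      tibble(focus_id = integer(0), class = character(0), y_px = numeric(0),
             x_px = numeric(0), radius_px = numeric(0), max_overlap = numeric(0),
             n_contacts = integer(0))

    # render channels
    psf_px <- (preset$psf_sigma_um %||% 0.15) / ps
    dapi <- matrix(preset$background, ny, nx)
    dapi[nucleus_mask] <- dapi[nucleus_mask] + preset$eu_intensity
    dapi <- dapi + (cc_labels > 0) * preset$cc_intensity
    dapi <- as.matrix(EBImage::gblur(EBImage::Image(dapi), sigma = psf_px))

    h3k <- matrix(preset$background, ny, nx)
    h3k[nucleus_mask] <- h3k[nucleus_mask] + 0.3 * preset$eu_intensity
    h3k <- h3k + (cc_labels > 0) * preset$cc_intensity * (preset$h3k9me3_scale %||% 1)
    h3k <- as.matrix(EBImage::gblur(EBImage::Image(h3k), sigma = psf_px))
    hp1 <- matrix(preset$background, ny, nx)
    hp1[nucleus_mask] <- hp1[nucleus_mask] + 0.3 * preset$eu_intensity
    hp1 <- hp1 + (cc_labels > 0) * preset$cc_intensity * (preset$hp1a_scale %||% 1)
    hp1 <- as.matrix(EBImage::gblur(EBImage::Image(hp1), sigma = psf_px))

    fish <- matrix(preset$background, ny, nx)
    ok <- foci[!is.na(foci$y_px), , drop = FALSE]
    if (nrow(ok)) {
      for (i in seq_len(nrow(ok))) {
        m <- disk_mask(ny, nx, ok$y_px[i], ok$x_px[i], r_rna)
        fish[m] <- fish[m] + preset$rna_intensity
      }
    }
    fish <- as.matrix(EBImage::gblur(EBImage::Image(fish), sigma = psf_px))

    ns <- preset$noise_sd %||% 0
    if (ns > 0) {
      dapi <- dapi + rnorm(ny * nx, sd = ns)
      fish <- fish + rnorm(ny * nx, sd = ns)
      h3k <- h3k + rnorm(ny * nx, sd = ns)
      hp1 <- hp1 + rnorm(ny * nx, sd = ns)
    }

    structure(
      list(dapi = dapi, fish = fish, h3k9me3 = h3k, hp1a = hp1,
           pixel_size_um = ps, nucleus_id = nucleus_id,
           truth = list(
             cc = tibble(cc_id = seq_len(n_cc),
                         y_px = cc_centers[, 1], x_px = cc_centers[, 2],
                         radius_px = cc_radii),
             foci = foci, cc_labels = cc_labels, nucleus_mask = nucleus_mask
           )),
      class = "rna_nucleus"
    )
  })
}
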