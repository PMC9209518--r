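# connected components for 2D or 3D masks; 3D by per-plane labelling and
# union-find merging of labels that overlap between adjacent planes
label_mask <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) {
    return(matrix(as.integer(EBImage::bwlabel(mask)), d[1], d[2]))
  }
  nz <- d[3]
  planes <- vector("list", nz)
  offset <- 0L
  for (z in seq_len(nz)) {
    l <- matrix(as.integer(EBImage::bwlabel(mask[, , z])), d[1], d[2])
    l[l > 0] <- l[l > 0] + offset
    offset <- max(offset, max(l))
    planes[[z]] <- l
  }
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (z in seq_len(nz - 1)) {
    a <- planes[[z]]; b <- planes[[z + 1]]
    both <- a > 0 & b > 0
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) union_(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- array(0L, d)
  for (z in seq_len(nz)) {
    l <- planes[[z]]
    pos <- l > 0
    l[pos] <- relabel[l[pos]]
    out[, , z] <- l
  }
  out
}

# drop labels with fewer than min_size voxels, relabel contiguously
filter_labels <- function(lab, min_size) {
  if (max(lab) == 0) return(lab)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_size)
  map <- rep(0L, length(tab))
  map[keep] <- seq_along(keep)
  pos <- lab > 0
  lab[pos] <- map[lab[pos]]
  lab
}

#' Segment nuclei and chromocenters
#'
#' Estimates the background as a percentile of the image, subtracts it, and
#' applies two constant thresholds (held fixed across a batch): a low one for
#' nuclei and a higher offset for the DAPI-bright chromocenter foci inside
#' them. Connected components below `min_area` are removed; each chromocenter
#' is assigned to its enclosing nucleus.
#'
#' @param image Numeric matrix `(y, x)` or array `(y, x, z)` of the
#'   segmentation channel (typically DAPI).
#' @param background_percentile Percentile of the image used as the
#'   background estimate (default 0.5).
#' @param nucleus_offset,cc_offset Constant thresholds above background for
#'   the nucleus and chromocenter masks. The exact constant is
#'   acquisition-dependent and must be supplied per batch.
#' @param min_area_nucleus,min_area_cc Minimum component sizes (pixels).
#'
#' @return A list of class `chromo_labels`: `nuclei` and `chromocenters`
#'   (integer label arrays, 0 = background), `cc_nucleus` (tibble mapping
#'   `cc_id` to `nucleus_id`), and `params`.
#' @export
segment_nuclei <- function(image, background_percentile = 0.5,
                           nucleus_offset, cc_offset,
                           min_area_nucleus = 200, min_area_cc = 5) {
  # background percentile is taken over out-of-nucleus pixels. The rough
  # nucleus mask comes from a two-stage Otsu: the first split isolates the
  # brightest class (chromocenters), the second separates extranuclear
  # background from nucleoplasm among the remaining pixels.
  otsu_thr <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(r[1])
    r[1] + EBImage::otsu(EBImage::Image(matrix((x - r[1]) / diff(r)))) * diff(r)
  }
  t1 <- otsu_thr(as.numeric(image))
  low <- image[image < t1]
  t2 <- if (length(low) > 1) otsu_thr(as.numeric(low)) else t1
  out_px <- image[image <= t2]
  if (!length(out_px)) out_px <- image
  bg <- quantile(out_px, background_percentile, names = FALSE)
  img <- image - bg
  nuc_mask <- img > nucleus_offset
  if (length(dim(image)) == 2) {
    nuc_mask <- EBImage::fillHull(nuc_mask) > 0
  }
  nuclei <- filter_labels(label_mask(nuc_mask), min_area_nucleus)
  if (max(nuclei) == 0) {
    warn("No nuclei found; returning empty label maps.")
    return(structure(list(nuclei = nuclei, chromocenters = nuclei * 0L,
                          cc_nucleus = tibble(cc_id = integer(0), nucleus_id = integer(0)),
                          params = list(background = bg)),
                     class = "chromo_labels"))
  }
  cc_mask <- (img > cc_offset) & (nuclei > 0)
  ccs <- filter_labels(label_mask(cc_mask), min_area_cc)
  cc_nucleus <- if (max(ccs) > 0) {
    purrr::map_dfr(seq_len(max(ccs)), function(l) {
      nid <- nuclei[ccs == l]
      tibble(cc_id = l, nucleus_id = as.integer(names(which.max(table(nid)))))
    })
  } else tibble(cc_id = integer(0), nucleus_id = integer(0))
  structure(list(nuclei = nuclei, chromocenters = ccs, cc_nucleus = cc_nucleus,
                 params = list(background = bg, nucleus_offset = nucleus_offset,
                               cc_offset = cc_offset)),
            class = "chromo_labels")
}

#' Chromocenter number per nucleus and its distribution
#'
#' @param labels A `chromo_labels` object (or a tibble with `nucleus_id`,
#'   `cc_id`) per image; pass a list for a batch, with `condition` names.
#' @return A list with `per_nucleus` (tibble: `condition`, `nucleus`,
#'   `n_chromocenters`), `histogram` (percentage of nuclei per count), and
#'   `test` (Mann-Whitney p between the first two conditions, when >= 2).
#' @export
chromocenter_count_histogram <- function(labels) {
  if (inherits(labels, "chromo_labels")) labels <- list(default = list(labels))
  per_nucleus <- purrr::imap_dfr(labels, function(images, cond) {
    purrr::imap_dfr(images, function(lb, i) {
      map <- if (inherits(lb, "chromo_labels")) lb$cc_nucleus else lb
      nuc_ids <- if (inherits(lb, "chromo_labels")) {
        setdiff(unique(as.integer(lb$nuclei)), 0L)
      } else unique(map$nucleus_id)
      counts <- table(factor(map$nucleus_id, levels = nuc_ids))
      tibble(condition = cond, image = i, nucleus = nuc_ids,
             n_chromocenters = as.integer(counts))
    })
  })
  if (!nrow(per_nucleus)) abort("No nuclei to summarize.")
  histogram <- per_nucleus |>
    dplyr::count(.data$condition, .data$n_chromocenters) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  conds <- unique(per_nucleus$condition)
  test <- if (length(conds) >= 2) {
    mw_test(per_nucleus$n_chromocenters[per_nucleus$condition == conds[1]],
            per_nucleus$n_chromocenters[per_nucleus$condition == conds[2]])
  } else NULL
  list(per_nucleus = per_nucleus, histogram = histogram, test = test)
}

# per-label mid-section: z-plane maximizing the label's area
optimal_plane <- function(lab, l) {
  d <- dim(lab)
  if (length(d) == 2) return(list(z = 1L, idx = which(lab == l, arr.ind = TRUE)))
  areas <- vapply(seq_len(d[3]), function(z) sum(lab[, , z] == l), integer(1))
  z <- which.max(areas)
  list(z = z, idx = which(lab[, , z] == l, arr.ind = TRUE))
}

#' Chromocenter morphometry at the optimal focal plane
#'
#' For each labelled chromocenter the mid-section is the z-plane maximizing
#' its cross-sectional area (single-plane images use that plane). Area is the
#' pixel count at the mid-section; the major axis is that of the
#' second-moment (covariance) ellipse of the mid-section pixels: axis length
#' \eqn{= 4\sqrt{\lambda}} for eigenvalue \eqn{\lambda}, exact for an ideal
#' ellipse.
#'
#' @param labels `chromo_labels` or an integer label array of chromocenters.
#' @param pixel_size_um Pixel size.
#' @return A tibble with `cc_id`, `nucleus_id` (when available), `optimal_z`,
#'   `area_px`, `area_um2`, `major_axis_um`, `minor_axis_um`, `centroid_y_px`,
#'   `centroid_x_px`.
#' @export
morphometry <- function(labels, pixel_size_um = 1) {
  cc_nucleus <- NULL
  lab <- labels
  if (inherits(labels, "chromo_labels")) {
    cc_nucleus <- labels$cc_nucleus
    lab <- labels$chromocenters
  }
  nl <- max(lab)
  if (nl == 0) return(tibble())
  out <- purrr::map_dfr(seq_len(nl), function(l) {
    op <- optimal_plane(lab, l)
    idx <- op$idx
    if (!nrow(idx)) return(tibble())
    a <- nrow(idx)
    cv <- stats::cov(idx) * (a - 1) / a  # population covariance
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 1 / 12)  # single-pixel rows still have finite extent
    tibble(
      cc_id = l,
      optimal_z = op$z,
      area_px = a,
      area_um2 = a * pixel_size_um^2,
      major_axis_um = 4 * sqrt(ev[1]) * pixel_size_um,
      minor_axis_um = 4 * sqrt(ev[2]) * pixel_size_um,
      centroid_y_px = mean(idx[, 1]),
      centroid_x_px = mean(idx[, 2])
    )
  })
  if (!is.null(cc_nucleus)) out <- dplyr::left_join(out, cc_nucleus, by = "cc_id")
  out
}

#' Mean channel intensity at each chromocenter's optimal focal plane
#'
#' @param channel Numeric array registered with the label map.
#' @param labels `chromo_labels` or chromocenter label array.
#' @return A tibble with `cc_id`, `optimal_z`, `mean_intensity`,
#'   `total_intensity`, `n_px`.
#' @export
intensity_at_foci <- function(channel, labels) {
  lab <- if (inherits(labels, "chromo_labels")) labels$chromocenters else labels
  if (!identical(dim(channel), dim(lab))) abort("Channel and label map dimensions differ.")
  nl <- max(lab)
  if (nl == 0) return(tibble())
  purrr::map_dfr(seq_len(nl), function(l) {
    op <- optimal_plane(lab, l)
    if (!nrow(op$idx)) return(tibble())
    vals <- if (length(dim(channel)) == 2) channel[op$idx] else channel[, , op$z][op$idx]
    tibble(cc_id = l, optimal_z = op$z, mean_intensity = mean(vals),
           total_intensity = sum(vals), n_px = length(vals))
  })
}

#' Pixelwise Pearson colocalization per chromocenter
#'
#' Pearson correlation between two channels over each chromocenter's pixels,
#' by default restricted to the mid-section plane. Chromocenters with fewer
#' than `min_px` pixels or zero variance in either channel are excluded (the
#' exclusion count is reported as an attribute).
#'
#' @param ch1,ch2 Numeric arrays (same dimensions).
#' @param labels `chromo_labels` or chromocenter label array.
#' @param midsection_only Restrict to the optimal focal plane (default TRUE).
#' @param min_px Minimum pixels per chromocenter (default 10).
#' @return A tibble with `cc_id`, `pearson_r`, `n_px`; attribute
#'   `n_excluded`.
#' @export
pearson_colocalization <- function(ch1, ch2, labels, midsection_only = TRUE,
                                   min_px = 10) {
  lab <- if (inherits(labels, "chromo_labels")) labels$chromocenters else labels
  nl <- max(lab)
  excluded <- 0L
  rows <- purrr::map_dfr(seq_len(nl), function(l) {
    if (midsection_only) {
      op <- optimal_plane(lab, l)
      if (length(dim(ch1)) == 2) {
        v1 <- ch1[op$idx]; v2 <- ch2[op$idx]
      } else {
        v1 <- ch1[, , op$z][op$idx]; v2 <- ch2[, , op$z][op$idx]
      }
    } else {
      sel <- lab == l
      v1 <- ch1[sel]; v2 <- ch2[sel]
    }
    if (length(v1) < min_px || sd(v1) == 0 || sd(v2) == 0) {
      excluded <<- excluded + 1L
      return(tibble())
    }
    tibble(cc_id = l, pearson_r = cor(v1, v2), n_px = length(v1))
  })
  attr(rows, "n_excluded") <- excluded
  rows
}

#' Intensity profile along a line
#'
#' Samples each channel along the segment `p0 -> p1` (pixel coordinates,
#' `c(y, x)`), averaging across `width_px` parallel offsets, then min-max
#' normalizes each channel to \[0, 1\]. A flat profile cannot be normalized
#' and is returned as zeros with a warning.
#'
#' @param channels A named list of numeric matrices (single plane each).
#' @param p0,p1 Endpoints in pixel coordinates `c(y, x)`.
#' @param width_px Averaging width perpendicular to the line.
#' @param pixel_size_um Pixel size for the output positions.
#' @return A tibble with `position_um`, `channel`, `intensity`.
#' @export
linescan <- function(channels, p0, p1, width_px = 1, pixel_size_um = 1) {
  if (is.matrix(channels)) channels <- list(channel1 = channels)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) abort("Degenerate line: endpoints coincide.")
  n <- max(2L, ceiling(len) + 1L)
  tt <- seq(0, 1, length.out = n)
  dir <- (p1 - p0) / len
  nrm <- c(-dir[2], dir[1])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = max(width_px, 1))
  bilinear <- function(img, y, x) {
    y0 <- floor(y); x0 <- floor(x)
    y0 <- pmin(pmax(y0, 1), nrow(img) - 1)
    x0 <- pmin(pmax(x0, 1), ncol(img) - 1)
    fy <- y - y0; fx <- x - x0
    img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
      img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
      img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
      img[cbind(y0 + 1, x0 + 1)] * fy * fx
  }
  purrr::imap_dfr(channels, function(img, nm) {
    prof <- rowMeans(vapply(offs, function(o) {
      y <- p0[1] + tt * len * dir[1] + o * nrm[1]
      x <- p0[2] + tt * len * dir[2] + o * nrm[2]
      bilinear(img, y, x)
    }, numeric(n)))
    rng <- range(prof)
    if (diff(rng) == 0) {
      warn(sprintf("Flat profile in channel '%s'; returning zeros.", nm))
      norm <- rep(0, n)
    } else {
      norm <- (prof - rng[1]) / diff(rng)
    }
    tibble(position_um = tt * len * pixel_size_um, channel = nm, intensity = norm)
  })
}

#' Quartile-binned comparison against a reference condition
#'
#' Bin boundaries are the quartiles of the reference condition; both
#' conditions' values are assigned to those bins (ties at a boundary fall in
#' the lower bin) and reported as fractions, together with a two-sided
#' Mann-Whitney test on the raw values.
#'
#' @param values Numeric vector.
#' @param condition Condition label per value.
#' @param reference Name of the condition defining the quartile boundaries
#'   (default: first level encountered).
#' @return A list with `fractions` (tibble: condition, quartile, fraction),
#'   `boundaries`, and `p_value`.
#' @export
quartile_bin <- function(values, condition, reference = NULL) {
  condition <- as.character(condition)
  reference <- reference %||% condition[1]
  if (!reference %in% condition) abort("`reference` condition not present.")
  q <- quantile(values[condition == reference], c(0.25, 0.5, 0.75), names = FALSE)
  bins <- cut(values, breaks = c(-Inf, q, Inf), labels = c("Q1", "Q2", "Q3", "Q4"),
              right = TRUE)
  fractions <- tibble(condition = condition, quartile = bins) |>
    dplyr::count(.data$condition, .data$quartile, .drop = FALSE) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  conds <- unique(condition)
  p <- if (length(conds) >= 2) {
    other <- setdiff(conds, reference)[1]
    mw_test(values[condition == reference], values[condition == other])
  } else NULL
  list(fractions = fractions, boundaries = q, p_value = p)
}
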