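test_that("overlap classification implements the 50% rules", {
  expect_equal(classify_overlap(c(0.8, 0)), "within")
  expect_equal(classify_overlap(c(0.3, 0.2)), "between")
  expect_equal(classify_overlap(c(0.3, 0)), "periphery")
  expect_equal(classify_overlap(numeric(0)), "unassociated")
  expect_equal(classify_overlap(c(0, 0)), "unassociated")
  # exactly 50% goes to the sub-50% branch
  expect_equal(classify_overlap(c(0.5)), "periphery")
  expect_equal(classify_overlap(c(0.5, 0.3)), "between")
  expect_error(classify_overlap(c(0.7, 0.6)), "sum")
  expect_error(classify_overlap(c(-0.1)), "\\[0, 1\\]")
})

test_that("classification is exhaustive and mutually exclusive over random fraction maps", {
  set.seed(99)
  for (i in 1:500) {
    k <- sample(0:4, 1)
    fr <- if (k == 0) numeric(0) else {
      raw <- runif(k)
      raw / max(sum(raw), 1) * runif(1)
    }
    cls <- classify_overlap(fr)
    expect_true(cls %in% c("within", "periphery", "between", "unassociated"))
    pos <- fr[fr > 0]
    ref <- if (!length(pos)) "unassociated"
      else if (max(pos) > 0.5) "within"
      else if (length(pos) >= 2) "between"
      else "periphery"
    expect_identical(cls, ref)
  }
})

test_that("generated nuclei satisfy their sampled class rule exactly", {
  probs_cases <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  want <- c("within", "periphery", "between")
  for (ci in seq_along(probs_cases)) {
    p <- chromodyn_preset("nucleus", "gfp_gapmer")
    p$rna_class_probs <- probs_cases[[ci]]
    p$rna_foci_count <- 3
    nuc <- make_rna_foci_nucleus(p, seed = 40 + ci)
    placed <- nuc$truth$foci[!is.na(nuc$truth$foci$y_px), ]
    expect_true(all(placed$class == want[ci]))
    # truth overlap fractions verify the class rule on the pixel grid
    for (r in seq_len(nrow(placed))) {
      sel <- disk_image(160, 160, placed$y_px[r], placed$x_px[r],
                        placed$radius_px[r]) > 0
      labs <- nuc$truth$cc_labels[sel]
      fr <- as.numeric(table(factor(labs[labs > 0],
                                    levels = seq_len(max(nuc$truth$cc_labels))))) / sum(sel)
      expect_identical(classify_overlap(fr), want[ci])
    }
  }
})

test_that("a focus centred deep inside a chromocenter overlaps it fully", {
  p <- chromodyn_preset("nucleus", "gfp_gapmer")
  p$rna_class_probs <- c(1, 0, 0)
  p$rna_foci_count <- 4
  nuc <- make_rna_foci_nucleus(p, seed = 3)
  placed <- nuc$truth$foci[!is.na(nuc$truth$foci$y_px), ]
  expect_true(all(placed$max_overlap > 0.6))
})

test_that("RNA focus detection finds planted foci and respects the threshold", {
  nuc <- make_rna_foci_nucleus("gfp_gapmer", seed = 17)
  n_true <- sum(!is.na(nuc$truth$foci$y_px))
  foci <- detect_rna_foci(nuc$fish, nuc$truth$nucleus_mask,
                          smoothing_sigma = 1, threshold = 60)
  expect_equal(max(foci), n_true)

  # foci well below threshold are not detected
  none <- detect_rna_foci(nuc$fish * 0.1, nuc$truth$nucleus_mask,
                          smoothing_sigma = 1, threshold = 60)
  expect_equal(max(none), 0)
  expect_error(detect_rna_foci(nuc$fish, matrix(0L, 160, 160), threshold = 60),
               "No nuclei")
})

test_that("end-to-end classification recovers the planted classes", {
  stats <- purrr::map_dfr(1:10, function(s) {
    nuc <- make_rna_foci_nucleus("gfp_gapmer", seed = 600 + s)
    labs <- segment_nuclei(nuc$dapi, nucleus_offset = 30, cc_offset = 140)
    foci <- detect_rna_foci(nuc$fish, labs$nuclei, smoothing_sigma = 1,
                            threshold = 60)
    recs <- classify_foci(foci, labs, pixel_size_um = nuc$pixel_size_um,
                          nucleus_id = s)
    truth <- nuc$truth$foci[!is.na(nuc$truth$foci$y_px), ]
    # match detected foci to truth by position
    det_pos <- purrr::map_dfr(seq_len(max(foci)), function(l) {
      px <- which(foci == l, arr.ind = TRUE)
      tibble::tibble(focus_id = l, y = mean(px[, 1]), x = mean(px[, 2]))
    })
    d <- sqrt(outer(det_pos$y, truth$y_px, "-")^2 + outer(det_pos$x, truth$x_px, "-")^2)
    nearest <- apply(d, 1, which.min)
    tibble::tibble(called = recs$class[match(det_pos$focus_id, recs$focus_id)],
                   truth = truth$class[nearest])
  })
  acc <- mean(stats$called == stats$truth)
  expect_gte(acc, 0.9)
})

test_that("foci prevalence reports proportions with a confidence interval", {
  recs <- tibble::tibble(condition = rep(c("gfp", "rnase"), each = 50),
                         n_foci = c(rpois(50, 5) + 1, rep(0, 50)))
  out <- foci_prevalence(recs)
  expect_equal(out$proportion[out$condition == "gfp"], 1)
  expect_equal(out$proportion[out$condition == "rnase"], 0)
  expect_true(all(out$ci_lo <= out$proportion & out$proportion <= out$ci_hi))
})
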