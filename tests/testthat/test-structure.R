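test_that("segmentation recovers planted foci and ignores blank images", {
  nuc <- make_rna_foci_nucleus("gfp_gapmer", seed = 5)
  labs <- segment_nuclei(nuc$dapi, nucleus_offset = 30, cc_offset = 140)
  expect_equal(max(labs$nuclei), 1)
  truth_n <- nrow(nuc$truth$cc)
  expect_equal(max(labs$chromocenters), truth_n)
  expect_true(all(labs$cc_nucleus$nucleus_id == 1))

  blank <- matrix(rnorm(100 * 100, 10, 1), 100, 100)
  expect_warning(empty <- segment_nuclei(blank, nucleus_offset = 30, cc_offset = 140),
                 "No nuclei")
  expect_equal(max(empty$nuclei), 0)
})

test_that("segmentation is invariant to an additive intensity offset", {
  nuc <- make_rna_foci_nucleus("gfp_gapmer", seed = 6)
  a <- segment_nuclei(nuc$dapi, nucleus_offset = 30, cc_offset = 140)
  b <- segment_nuclei(nuc$dapi + 500, nucleus_offset = 30, cc_offset = 140)
  expect_identical(a$chromocenters, b$chromocenters)
})

test_that("chromocenter pixels are nested inside their nucleus", {
  nuc <- make_rna_foci_nucleus("gfp_gapmer", seed = 7)
  labs <- segment_nuclei(nuc$dapi, nucleus_offset = 30, cc_offset = 140)
  expect_true(all(labs$nuclei[labs$chromocenters > 0] > 0))
})

test_that("count histogram separates conditions with different focus numbers", {
  counts <- list(
    low = list(tibble::tibble(nucleus_id = rep(1:50, each = 1), cc_id = 1:50)),
    high = list(tibble::tibble(nucleus_id = rep(1:50, times = 3), cc_id = 1:150))
  )
  # build per-nucleus maps directly: low = 1 cc/nucleus, high = 3 cc/nucleus
  out <- chromocenter_count_histogram(counts)
  expect_lt(out$test, 1e-6)
  hist_low <- out$histogram[out$histogram$condition == "low", ]
  expect_equal(hist_low$n_chromocenters, 1)
  expect_equal(hist_low$percent, 100)
})

test_that("morphometry matches analytic geometry on rendered primitives", {
  # disk of radius 10: area ~ pi * 100, major axis ~ 20
  img <- disk_image(64, 64, 32, 32, 10)
  lab <- matrix(as.integer(img > 0), 64, 64)
  m <- morphometry(lab, pixel_size_um = 1)
  expect_true(abs(m$area_px - 314) <= 5)
  expect_equal(m$major_axis_um, 20, tolerance = 0.06)
  expect_equal(m$minor_axis_um, 20, tolerance = 0.06)

  # axis-aligned ellipse with semi-axes (10, 5): major 20, minor 10
  yy <- matrix(seq_len(64), 64, 64); xx <- t(yy)
  ell <- matrix(as.integer(((yy - 32) / 10)^2 + ((xx - 32) / 5)^2 <= 1), 64, 64)
  me <- morphometry(ell, pixel_size_um = 0.5)
  expect_equal(me$major_axis_um, 20 * 0.5, tolerance = 0.05)
  expect_equal(me$minor_axis_um, 10 * 0.5, tolerance = 0.05)

  # sphere in a 3D stack: optimal plane is the equator
  arr <- array(0L, c(41, 41, 21))
  for (z in 1:21) {
    r2 <- 8^2 - ((z - 11) * 2)^2
    if (r2 > 0) arr[, , z] <- as.integer(disk_image(41, 41, 21, 21, sqrt(r2)) > 0)
  }
  ms <- morphometry(arr, pixel_size_um = 1)
  expect_equal(ms$optimal_z, 11)
  expect_equal(ms$area_px, pi * 64, tolerance = 0.05)
})

test_that("focal-plane intensities report channel means over label pixels", {
  lab <- matrix(0L, 20, 20); lab[5:8, 5:8] <- 1L; lab[14:16, 14:16] <- 2L
  chan <- matrix(7, 20, 20)
  out <- intensity_at_foci(chan, lab)
  expect_equal(out$mean_intensity, c(7, 7))
  # identity: measuring the label image itself returns in-label means
  self <- intensity_at_foci(lab * 10, lab)
  expect_equal(self$mean_intensity, c(10, 20))
})

test_that("Pearson colocalization matches closed forms", {
  lab <- matrix(1L, 100, 100)
  set.seed(3)
  ch1 <- matrix(rnorm(1e4), 100, 100)
  expect_equal(pearson_colocalization(2 * ch1 + 5, ch1, lab)$pearson_r, 1)
  expect_equal(pearson_colocalization(-ch1, ch1, lab)$pearson_r, -1)
  # additive noise: rho = 1 / sqrt(1 + sigma^2 / var)
  ch2 <- ch1 + matrix(rnorm(1e4), 100, 100)
  expect_equal(pearson_colocalization(ch1, ch2, lab)$pearson_r,
               1 / sqrt(2), tolerance = 0.02)
  # zero variance excluded with a count
  out <- pearson_colocalization(matrix(1, 100, 100), ch1, lab)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("linescans are symmetric across a symmetric blob and guard degeneracy", {
  img <- matrix(0, 51, 51)
  img <- render_blobs_for_test(img, 26, 26, amp = 100, sigma = 5)
  prof <- linescan(list(g = img), p0 = c(26, 6), p1 = c(26, 46), pixel_size_um = 0.2)
  expect_equal(which.max(prof$intensity), ceiling(nrow(prof) / 2), tolerance = 1)
  expect_equal(max(prof$intensity), 1)
  expect_equal(min(prof$intensity), 0)
  # symmetry
  v <- prof$intensity
  expect_lt(max(abs(v - rev(v))), 0.05)

  # two concentric blobs: the narrower channel has the smaller FWHM
  inner <- render_blobs_for_test(matrix(0, 51, 51), 26, 26, 100, 3)
  both <- linescan(list(wide = img, narrow = inner), c(26, 6), c(26, 46))
  fwhm <- function(ch) sum(both$intensity[both$channel == ch] > 0.5)
  expect_lt(fwhm("narrow"), fwhm("wide"))

  expect_warning(flat <- linescan(list(f = matrix(5, 20, 20)), c(10, 2), c(10, 18)),
                 "Flat")
  expect_true(all(flat$intensity == 0))
  expect_error(linescan(list(f = img), c(5, 5), c(5, 5)), "Degenerate")
})

test_that("quartile binning uses reference boundaries and lower-bin ties", {
  set.seed(11)
  ctrl <- rnorm(2000)
  qb <- quartile_bin(c(ctrl, ctrl), rep(c("ctrl", "also_ctrl"), each = 2000),
                     reference = "ctrl")
  expect_equal(qb$fractions$fraction, rep(0.25, 8), tolerance = 1e-9)

  shifted <- quartile_bin(c(ctrl, ctrl + 100), rep(c("ctrl", "trt"), each = 2000),
                          reference = "ctrl")
  top <- shifted$fractions
  expect_equal(top$fraction[top$condition == "trt" & top$quartile == "Q4"], 1)

  # normal-theory oracle for a +0.5 SD shift: P(Z + 0.5 > q75)
  set.seed(12)
  big <- rnorm(20000); trt <- rnorm(20000) + 0.5
  qb2 <- quartile_bin(c(big, trt), rep(c("ctrl", "trt"), each = 20000), "ctrl")
  expected_top <- 1 - pnorm(qnorm(0.75) - 0.5)
  got <- qb2$fractions$fraction[qb2$fractions$condition == "trt" &
                                  qb2$fractions$quartile == "Q4"]
  expect_equal(got, expected_top, tolerance = 0.03)
  expect_lt(qb2$p_value, 1e-10)

  # exact boundary value falls in the lower bin
  qb3 <- quartile_bin(c(1, 2, 3, 4, 2), c(rep("a", 4), "b"), reference = "a")
  frac_b <- qb3$fractions[qb3$fractions$condition == "b", ]
  expect_equal(frac_b$fraction[frac_b$quartile == "Q2"], 1)
})
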