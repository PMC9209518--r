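test_that("synthetic FRAP traces are deterministic and respect the preset", {
  tr1 <- make_frap_trace("tale_ctrl", seed = 11)
  tr2 <- make_frap_trace("tale_ctrl", seed = 11)
  expect_identical(tr1$i_bleached, tr2$i_bleached)
  expect_identical(attr(tr1, "bleach_frame"), 11L)

  # noiseless construction: corrected curve sits at bleach_depth right after
  # the bleach and at 1 before it
  cv <- noiseless_curve("tale_ctrl")
  bf <- attr(cv, "bleach_frame")
  expect_equal(cv$intensity[seq_len(bf - 1)], rep(1, bf - 1), tolerance = 1e-12)
  expect_equal(cv$intensity[bf], 0.30, tolerance = 1e-9)

  # no recovery when the mobile fraction is zero
  p <- chromodyn_preset("frap", "tale_ctrl")
  p$mobile_fraction <- 0
  p$noise_sd <- 0
  cv0 <- correct_trace(make_frap_trace(p, seed = 1))
  post <- cv0$intensity[attr(cv0, "bleach_frame"):nrow(cv0)]
  expect_equal(post, rep(p$bleach_depth, length(post)), tolerance = 1e-9)

  expect_error(make_frap_trace(modifyList(p, list(k_per_s = NaN))), "finite")
  expect_error(make_frap_trace(modifyList(p, list(mobile_fraction = 1.4))), "\\[0, 1")
})

test_that("control-ROI correction removes the acquisition-bleaching trend", {
  # identical bleached and control ROIs normalize to exactly 1
  tr <- make_frap_trace("hp1a_ctrl", seed = 3, noise_sd = 0)
  tr$i_bleached <- tr$i_control
  cv <- correct_trace(tr)
  expect_equal(cv$intensity, rep(1, nrow(cv)), tolerance = 1e-12)

  # with acquisition bleaching on, the corrected fit recovers the generative
  # plateau; without the control the plateau is biased low
  trb <- make_frap_trace("hp1a_ctrl", seed = 3, noise_sd = 0)
  gt <- attr(trb, "ground_truth")
  fit_on <- fit_recovery(correct_trace(trb, use_control = TRUE))
  expect_equal(fit_on$plateau, gt$plateau, tolerance = 1e-3)
  fit_off <- fit_recovery(correct_trace(trb, use_control = FALSE))
  expect_lt(fit_off$plateau, gt$plateau)

  # failure modes are loud and name the frame
  bad <- make_frap_trace("hp1a_ctrl", seed = 3)
  bad$i_control[5] <- bad$i_background[5] - 1
  expect_error(correct_trace(bad), "frame 5")
})

test_that("one-phase association fit recovers exact parameters on its model class", {
  tt <- seq(0, 120, by = 1)
  y <- 0.3 + (0.85 - 0.3) * (1 - exp(-0.0866 * tt))
  fit <- fit_recovery(c(1, 1, y), time_s = c(-2, -1, tt), bleach_frame = 3)
  expect_true(fit$converged)
  expect_equal(fit$y0, 0.3, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.85, tolerance = 1e-6)
  expect_equal(fit$k_per_s, 0.0866, tolerance = 1e-6)
  expect_equal(fit$t_half_s, log(2) / fit$k_per_s, tolerance = 1e-12)

  # flat post-bleach curve: plateau collapses to y0, mobile ~ 0
  flat <- fit_recovery(c(1, 1, rep(0.3, 30)), time_s = seq(-2, 27), bleach_frame = 3)
  expect_equal(flat$plateau, flat$y0, tolerance = 1e-6)
  expect_lt(flat$mobile_fraction, 1e-6)

  expect_error(
    fit_recovery(c(1, 1, y[1:5]), time_s = c(-2, -1, tt[1:5]), bleach_frame = 3),
    "8 post-bleach"
  )
})

test_that("half-time and fractions follow their defining formulas", {
  expect_equal(half_time(log(2)), 1.0)
  expect_equal(half_time(0.0866), 8.004, tolerance = 1e-3)
  expect_equal(half_time(0.0533), 13.006, tolerance = 1e-3)
  expect_error(half_time(0), "> 0")

  fr <- frap_fractions(pre_bleach = 1, first_post = 0.3, plateau = 0.825)
  expect_equal(fr$mobile, 0.75)
  expect_equal(fr$immobile, 0.25)
  expect_equal(frap_fractions(pre_bleach = 1, first_post = 0.3, plateau = 1)$mobile, 1)
  expect_equal(frap_fractions(pre_bleach = 1, first_post = 0.3, plateau = 0.3)$mobile, 0)
  expect_error(frap_fractions(pre_bleach = 0.2, first_post = 0.3, plateau = 0.5), "exceed")
  expect_warning(frap_fractions(pre_bleach = 1, first_post = 0.3, plateau = 1.05), "clamped")
})

test_that("fractions are invariant under affine rescaling of raw intensities", {
  tr <- make_frap_trace("hp1a_msr", seed = 9)
  gain <- 3.7; offset <- 55
  tr2 <- tr
  for (col in c("i_bleached", "i_control", "i_background")) {
    tr2[[col]] <- gain * tr[[col]] + offset
  }
  attr(tr2, "bleach_frame") <- attr(tr, "bleach_frame")
  f1 <- fit_recovery(correct_trace(tr))
  f2 <- fit_recovery(correct_trace(structure(tr2, class = class(tr),
                                             bleach_frame = attr(tr, "bleach_frame"))))
  expect_equal(f1$mobile_fraction, f2$mobile_fraction, tolerance = 1e-6)
  expect_equal(f1$t_half_s, f2$t_half_s, tolerance = 1e-6)
})

test_that("noiseless fits match the generative parameters for every preset", {
  for (nm in chromodyn_preset("frap")) {
    tr <- make_frap_trace(nm, seed = 1, noise_sd = 0)
    gt <- attr(tr, "ground_truth")
    fit <- fit_recovery(correct_trace(tr))
    expect_equal(fit$y0, gt$y0, tolerance = 1e-6, label = nm)
    expect_equal(fit$plateau, gt$plateau, tolerance = 1e-6, label = nm)
    expect_equal(fit$k_per_s, gt$k_per_s, tolerance = 1e-6, label = nm)
    expect_equal(fit$mobile_fraction + fit$immobile_fraction, 1, tolerance = 1e-12)
  }
})

test_that("condition summaries report medians and a Mann-Whitney contrast", {
  fits <- c(
    lapply(1:12, function(s) fit_recovery(correct_trace(make_frap_trace("hp1a_ctrl", seed = s)))),
    lapply(1:12, function(s) fit_recovery(correct_trace(make_frap_trace("hp1a_msr", seed = 100 + s))))
  )
  out <- summarize_frap(fits, rep(c("ctrl", "msr"), each = 12))
  expect_setequal(unique(out$summary$quantity),
                  c("t_half_s", "mobile_fraction", "immobile_fraction"))
  p_th <- out$tests$p_value[out$tests$quantity == "t_half_s"]
  expect_lt(p_th, 0.05)

  single <- summarize_frap(fits[1:12], rep("ctrl", 12))
  expect_null(single$tests)
})

test_that("Mann-Whitney p-values are exact for small samples without ties", {
  # enumeration over all 20 rank assignments gives one-sided 1/20, two-sided 0.1
  expect_equal(mw_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mw_test(c(7, 8, 9), c(1, 2, 3)), 0.1)
  # identical groups: no evidence of a shift (tie-corrected approximation)
  expect_equal(mw_test(c(1, 2, 3), c(1, 2, 3)), 1)
})
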