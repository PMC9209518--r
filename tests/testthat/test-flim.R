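test_that("TCSPC histograms are deterministic multinomial draws of the decay", {
  h1 <- make_flim_histogram(2, 1e5, seed = 4)
  h2 <- make_flim_histogram(2, 1e5, seed = 4)
  expect_identical(h1$counts, h2$counts)
  expect_equal(sum(h1$counts), 1e5)
  expect_error(make_flim_histogram(2, 0), ">= 1")
  expect_error(make_flim_histogram(-1, 100), "> 0")
  expect_error(make_flim_histogram(2, 100, bin_width_ns = 1, n_bins = 256),
               "repetition period")

  # very long lifetime: counts approach uniform over the window
  hu <- make_flim_histogram(1e6, 2e5, seed = 1)
  expect_gt(chisq.test(hu$counts)$p.value, 0.01)
})

test_that("lifetime fits recover the generative tau within 1% at high counts", {
  for (tau in c(0.5, 2, 4)) {
    h <- make_flim_histogram(tau, 1e6, seed = round(tau * 10))
    fit <- pool_and_fit(h)
    expect_true(fit$converged)
    expect_lt(abs(fit$tau_ns - tau) / tau, 0.01)
  }
})

test_that("wraparound keeps the estimator unbiased for lifetimes up to 5 ns", {
  # at tau = 5 ns, ~0.7% of the decay wraps past the 25 ns period
  taus <- vapply(1:25, function(s) {
    pool_and_fit(make_flim_histogram(5, 2e5, seed = s))$tau_ns
  }, numeric(1))
  expect_lt(abs(mean(taus) - 5) / 5, 0.02)
})

test_that("pooling histograms equals fitting the summed histogram", {
  hs <- lapply(1:5, function(s) make_flim_histogram(2.2, 5e4, seed = s))
  pooled <- pool_and_fit(hs)
  summed <- hs[[1]]
  summed$counts <- Reduce(`+`, lapply(hs, function(h) h$counts))
  expect_equal(pooled$tau_ns, pool_and_fit(summed)$tau_ns, tolerance = 1e-10)
  expect_equal(pooled$n_photons, 2.5e5)
})

test_that("fits with a Gaussian IRF still recover the lifetime", {
  n_bins <- 256
  tt <- (seq_len(n_bins) - 0.5) * 25 / n_bins
  irf <- exp(-(tt - 2)^2 / (2 * 0.25^2))
  h <- make_flim_histogram(2.5, 1e6, irf = irf, seed = 8)
  fit <- pool_and_fit(h, irf = irf)
  expect_lt(abs(fit$tau_ns - 2.5) / 2.5, 0.03)
})

test_that("low photon counts are refused rather than fitted", {
  h <- make_flim_histogram(2, 500, seed = 1)
  expect_error(pool_and_fit(h), "below floor")
})

test_that("the generative heterochromatin/euchromatin ordering is preserved", {
  fl <- chromodyn_preset("flim", "sirdna")
  ok <- vapply(1:30, function(s) {
    het <- pool_and_fit(make_flim_histogram(fl$tau_het_ns$gfp_gapmer, 1e5,
                                            seed = s, region_label = "het"))
    eu <- pool_and_fit(make_flim_histogram(fl$tau_eu_ns$gfp_gapmer, 1e5,
                                           seed = 1000 + s, region_label = "eu"))
    het$tau_ns < eu$tau_ns
  }, logical(1))
  expect_true(all(ok))
})

test_that("two-level masks split nuclei into disjoint exhaustive regions", {
  im <- make_flim_image("gfp_gapmer", seed = 12)
  mask <- build_two_level_mask(im$intensity, im$nuclei, spot_sigma = 4)
  expect_false(any(mask$het & mask$eu))
  expect_true(all(xor(mask$het, mask$eu) == (im$nuclei > 0)))
  # called heterochromatin overlaps the truth spots (IoU)
  iou <- sum(mask$het & im$truth_het) / sum(mask$het | im$truth_het)
  expect_gte(iou, 0.7)

  flat <- matrix(10, 80, 80)
  nuc <- matrix(0L, 80, 80); nuc[20:60, 20:60] <- 1L
  expect_warning(m2 <- build_two_level_mask(flat, nuc, spot_sigma = 3,
                                            spot_threshold = 5), "No heterochromatin")
  expect_equal(sum(m2$het), 0)
})

test_that("condition comparison uses per-image lifetimes and guards tiny arms", {
  fl <- chromodyn_preset("flim", "sirdna")
  sim_arm <- function(cond, n_img, seed0) {
    purrr::map_dfr(seq_len(n_img), function(i) {
      dplyr::bind_rows(
        pool_and_fit(make_flim_histogram(fl$tau_het_ns[[cond]], 5e4,
                                         seed = seed0 + i, region_label = "het"),
                     region_label = "het", image_id = i),
        pool_and_fit(make_flim_histogram(fl$tau_eu_ns[[cond]], 5e4,
                                         seed = seed0 + 500 + i, region_label = "eu"),
                     region_label = "eu", image_id = i)
      ) |> dplyr::mutate(condition = cond)
    })
  }
  lifetimes <- dplyr::bind_rows(sim_arm("gfp_gapmer", 10, 0),
                                sim_arm("msr_gapmer", 10, 100))
  out <- compare_flim_conditions(lifetimes)
  expect_equal(nrow(out$summary), 4)
  p_het <- out$tests$p_value[out$tests$region_label == "het"]
  expect_lt(p_het, 0.05)

  single <- compare_flim_conditions(lifetimes[lifetimes$image_id == 1, ])
  expect_null(single$tests)
})
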