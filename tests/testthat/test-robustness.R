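test_that("noise injection touches only post-stimulus samples", {
  e <- small_cohort()$epochs[[1]]
  pert <- inject_noise(e, scale = 1.5, target = "high", seed = 3)
  pre <- e$times < 0
  expect_identical(pert$data[, pre], e$data[, pre])
  # untargeted trials are untouched
  lo <- e$condition == "low"
  expect_identical(pert$data[lo, ], e$data[lo, ])
  # targeted trials do change after stimulus onset
  expect_gt(max(abs(pert$data[!lo, !pre] - e$data[!lo, !pre])), 0.1)
  # scale zero is the exact identity
  expect_identical(inject_noise(e, 0, "both", seed = 3), e)
  expect_error(inject_noise(e, 1, "bogus", seed = 1), "absent")
})

test_that("injected noise variance grows as the square of the scale", {
  e <- small_cohort()$epochs[[2]]
  added <- function(scale) {
    p <- inject_noise(e, scale, "both", seed = 11)
    v <- p$data - e$data
    mean(v[, e$times >= 0]^2)
  }
  expect_lt(abs(added(2) / added(1) - 4), 0.4)   # ratio 4 within 10%
})

test_that("heavy noise on one condition inflates its variability track", {
  sim <- small_cohort()
  infl <- vapply(sim$epochs, function(e) {
    pert <- inject_noise(e, 2, "high", seed = 21)
    tr0 <- sliding_track(e, "tempSD", step_ms = 25)
    tr2 <- sliding_track(pert, "tempSD", step_ms = 25)
    post <- tr0$times >= 0
    hi <- e$condition == "high"
    mean(tr2$values[hi, post]) / mean(tr0$values[hi, post])
  }, 0)
  expect_gt(mean(infl), 1.3)
})

test_that("the default sweep enumerates 11 scales and keeps mild-noise support", {
  mt <- mid_tracks()
  sim <- mid_cohort()
  cfgn <- noise_config(target = "high", seed = 5)
  expect_length(cfgn$scales, 11)
  sw <- noise_sweep(sim$epochs, mt$scores, cfgn)
  expect_equal(nrow(sw), 11)
  expect_equal(sw$scale, seq(0, 2, by = 0.2))
  # mild noise (scale <= 1) does not abolish the planted partial correlation
  expect_true(all(sw$supported[sw$scale <= 1]))
  expect_error(noise_config(scales = -1), ">= 0")
  expect_error(noise_config(baseline_interval = c(0, 100)), "pre-stimulus")
})

test_that("a null cohort draws no support at any noise scale", {
  sim0 <- generate_cohort(generator_config(
    n_subjects = 30, n_trials_per_condition = 8, rho_var_discrim = 0,
    rho_amp_discrim = 0, seed = 71))
  sc0 <- discrim_scores(sim0$ratings)
  sw <- noise_sweep(sim0$epochs, sc0,
                    noise_config(scales = c(0, 1, 2), target = "both",
                                 seed = 6))
  expect_false(any(sw$supported))
})

test_that("power maps detect strong effects and stay at alpha under the null", {
  mt <- mid_tracks()
  sim <- mid_cohort()
  pm <- power_map(sim$epochs, mt$scores, axis = "subjects",
                  sizes = c(10, 40), n_reps = 40, seed = 2)
  peak <- which.max(colMeans(mt$dvar$delta)[mt$dvar$times >= 0])
  expect_gt(pm$prob[2, peak], 0.8)            # full-size detection
  expect_gte(pm$prob[2, peak], pm$prob[1, peak])
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  # null cohort: significance probability stays near the FDR level
  sim0 <- generate_cohort(generator_config(
    n_subjects = 30, n_trials_per_condition = 8, rho_var_discrim = 0,
    rho_amp_discrim = 0, seed = 72))
  sc0 <- discrim_scores(sim0$ratings)
  pm0 <- power_map(sim0$epochs, sc0, axis = "subjects", sizes = 30,
                   n_reps = 60, seed = 3)
  # bootstrap duplicates make per-resample tests mildly anticonservative,
  # so the null rate sits somewhat above the nominal 0.05 FDR level
  expect_lt(mean(pm0$prob), 0.15)
  expect_lt(max(pm0$prob), 0.4)
  expect_error(power_map(sim$epochs, mt$scores, axis = "subjects",
                         sizes = 100, n_reps = 5), "exceed")
})

test_that("trial resampling power grows with the trial count", {
  mt <- mid_tracks()
  sim <- mid_cohort()
  pm <- power_map(sim$epochs, mt$scores, axis = "trials",
                  sizes = c(2, 6, 10), n_reps = 40, seed = 4)
  peak <- which.max(colMeans(mt$dvar$delta)[mt$dvar$times >= 0])
  probs <- pm$prob[, peak]
  expect_gt(cor(pm$sizes, probs, method = "spearman"), 0)
})

test_that("minimal size extraction follows the 80% contour", {
  fake <- structure(list(axis = "trials", sizes = c(2, 4, 6),
                         times = c(100, 200, 300),
                         prob = rbind(c(0, 0, 0.5), c(0, 0.85, 0.7),
                                      c(0.2, 0.9, 0.95)),
                         contour80 = NULL), class = "power_map")
  ms <- min_size_for_power(fake)
  expect_equal(ms, c(NA, 4, 6))
  none <- fake; none$prob <- matrix(0, 3, 3)
  expect_true(all(is.na(min_size_for_power(none))))
})
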