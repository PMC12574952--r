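test_that("temporal SD follows the population formula", {
  expect_equal(temporal_sd(rep(3, 10)), 0)
  expect_equal(temporal_sd(c(0, 0, 0, 4)), sqrt(3))
  x <- rnorm(50)
  expect_equal(temporal_sd(2.5 * x), 2.5 * temporal_sd(x))
  expect_error(temporal_sd(1), "at least 2")
})

test_that("temporal SD matches an independent two-pass oracle", {
  set.seed(11)
  for (n in c(2, 5, 100, 1500)) {
    x <- rnorm(n, mean = runif(1, -50, 50), sd = runif(1, 0.1, 20))
    expect_equal(temporal_sd(x), two_pass_sd(x), tolerance = 1e-12)
  }
})

test_that("coefficient of variation flags near-zero means", {
  expect_identical(coefficient_of_variation(c(-1, 1)), Inf)
  expect_equal(coefficient_of_variation(c(2, 2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)
})

test_that("ordinal pattern extraction counts and codes embedding vectors", {
  expect_length(ordinal_patterns(rnorm(100), m = 4, tau = 1), 97)
  expect_length(ordinal_patterns(rnorm(20), m = 3, tau = 2), 16)
  # a strictly increasing series has a single pattern
  expect_length(unique(ordinal_patterns(1:50, m = 4)), 1)
  expect_error(ordinal_patterns(1:3, m = 4, tau = 2), "too short")
  expect_error(ordinal_patterns(1:10, m = 1), "m must be >= 2")
})

test_that("permutation entropy matches exhaustive enumeration", {
  expect_equal(permutation_entropy(1:100), 0)
  x <- c(3, 1, 2, 5, 4)
  expect_equal(permutation_entropy(x, m = 3, tau = 1),
               pe_enumerate(x, 3, 1))
  set.seed(21)
  for (i in 1:10) {
    y <- sample(20)            # ties impossible
    expect_equal(permutation_entropy(y, m = 3, tau = 1),
                 pe_enumerate(y, 3, 1))
    expect_equal(permutation_entropy(y, m = 4, tau = 2),
                 pe_enumerate(y, 4, 2))
  }
})

test_that("permutation entropy is rank-based and bounded", {
  set.seed(5)
  x <- rnorm(300)
  pe <- permutation_entropy(x)
  expect_equal(permutation_entropy(exp(2 * x) + 7), pe)  # monotone transform
  expect_gte(pe, 0)
  expect_lte(pe, log(factorial(4)))
  # iid continuous noise approaches the log(m!) ceiling in long windows
  z <- rnorm(10000)
  expect_equal(permutation_entropy(z), log(factorial(4)), tolerance = 0.02)
})

test_that("sliding tracks have centered full-window geometry", {
  e <- epoch_set(matrix(5, 2, 1500), seq(-500, 999), c("low", "high"))
  tr <- sliding_track(e, "tempSD")
  expect_equal(ncol(tr$values), 1401)
  expect_true(all(tr$values == 0))
  expect_equal(tr$times[1], -450.5)
  expect_equal(tr$times[1401], 949.5)
  expect_error(sliding_track(e, "bogus"), "arg")
})

test_that("amplitude track peaks near the evoked template peaks", {
  times <- seq(-500, 999)
  tpl <- erp_template(times)
  e <- epoch_set(rbind(tpl, tpl), times, c("low", "high"))
  tr <- sliding_track(e, "amplitude")
  expect_lt(abs(tr$times[which.max(tr$values[1, ])] - 400), 50)
  expect_lt(abs(tr$times[which.min(tr$values[1, ])] - 200), 50)
})

test_that("rolling metrics are partition-consistent when step equals window", {
  set.seed(9)
  x <- rnorm(600)
  e <- epoch_set(matrix(x, 1), seq(-100, 499), "low")
  for (met in c("tempSD", "amplitude", "PE")) {
    tr <- sliding_track(e, met, window_ms = 100, step_ms = 100)
    blocks <- split(x, rep(1:6, each = 100))
    ref <- vapply(blocks, switch(met, tempSD = temporal_sd,
                                 amplitude = mean,
                                 PE = permutation_entropy), 0)
    expect_equal(unname(tr$values[1, ]), unname(ref), tolerance = 1e-10)
  }
})

test_that("condition averaging and differencing behave", {
  e <- epoch_set(matrix(rnorm(6000), 4), seq(-500, 999),
                 c("low", "low", "high", "high"))
  tr <- sliding_track(e, "tempSD", step_ms = 10)
  lo <- condition_average(tr, "low")
  hi <- condition_average(tr, "high")
  expect_equal(nrow(lo$values), 1)
  d <- diff_track(hi, lo)
  expect_equal(d$condition, "diff")
  expect_equal(d$values, hi$values - lo$values)
  expect_equal(diff_track(hi, hi)$values, 0 * hi$values)
  single <- condition_average(sliding_track(subset_trials(e, c(1, 3)),
                                            "tempSD", step_ms = 10), "low")
  expect_equal(single$values[1, ],
               sliding_track(subset_trials(e, 1), "tempSD",
                             step_ms = 10)$values[1, ])
  tr2 <- sliding_track(e, "tempSD", window_ms = 50, step_ms = 10)
  expect_error(diff_track(condition_average(tr2, "high"), lo), "geometry")
})

test_that("induced responses have zero trial average yet keep variability", {
  e <- small_cohort()$epochs[[1]]
  ind <- induced_epochs(e)
  for (cond in unique(ind$condition)) {
    avg <- colMeans(ind$data[ind$condition == cond, , drop = FALSE])
    expect_lt(max(abs(avg)), 1e-9)
  }
  # two identical trials per condition -> all-zero induced data
  x <- matrix(rnorm(3000), 2, 1500, byrow = FALSE)
  e2 <- epoch_set(rbind(x[1, ], x[1, ], x[2, ], x[2, ]), seq(-500, 999),
                  rep(c("low", "high"), each = 2))
  expect_equal(max(abs(induced_epochs(e2)$data)), 0)
  expect_error(induced_epochs(epoch_set(x, seq(-500, 999), c("low", "high"))),
               "fewer than 2")
})

test_that("induced variability still carries the planted gain", {
  sim <- small_cohort()
  ind <- lapply(sim$epochs, induced_epochs)
  dv <- cohort_diff_tracks(ind, "tempSD", window_ms = 100, step_ms = 10)
  roi <- peak_roi(list(times = dv$times, values = dv$mean))
  expect_gt(mean(roi_value(list(times = dv$times, values = dv$delta), roi)), 0)
})

test_that("peak ROI selection is centered, bounded and mode-aware", {
  times <- seq(-450.5, 949.5)
  v <- exp(-0.5 * ((times - 310) / 60)^2)
  roi <- peak_roi(list(times = times, values = v))
  expect_equal(unname(attr(roi, "peak_ms")), 309.5)  # nearest window center
  expect_equal(as.numeric(roi), c(299.5, 319.5))
  expect_length(which(times >= roi[1] & times <= roi[2]), 21)
  # trough mode picks the minimum (permutation-entropy convention)
  roi_min <- peak_roi(list(times = times, values = -v), mode = "min")
  expect_equal(unname(attr(roi_min, "peak_ms")), 309.5)
  # pre-stimulus extrema are ignored
  v2 <- v; v2[times < 0] <- 10
  expect_equal(unname(attr(peak_roi(list(times = times, values = v2)),
                           "peak_ms")), 309.5)
  expect_warning(peak_roi(list(times = times, values = rep(1, length(times)))),
                 "constant")
  expect_equal(roi_value(list(times = times, values = v), roi),
               mean(v[times >= roi[1] & times <= roi[2]]))
})
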