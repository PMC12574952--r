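test_that("the worked matching windows admit exactly the in-tolerance candidates", {
  pain <- data.frame(subject_id = "p1", high = 6, low = 4)
  other <- data.frame(subject_id = c("t1", "t2", "t3", "t4"),
                      high = c(6.4, 6.6, 5.5, 6.0),
                      low = c(4.4, 4.0, 3.5, 4.6))
  # t2 fails the high window (6.6 > 6.5), t4 fails the low window
  mr <- match_ratings(pain, other, tol = 0.5, seed = 1)
  expect_equal(nrow(mr$pairs), 1)
  expect_true(mr$pairs$other_id %in% c("t1", "t3"))
  # t3 has total error 0.9, t1 has 0.8 -> t1 is the unique minimiser
  expect_equal(mr$pairs$other_id, "t1")
})

test_that("an exact candidate is paired deterministically with zero error", {
  pain <- data.frame(subject_id = "p1", high = 6, low = 4)
  other <- data.frame(subject_id = c("t1", "t2"), high = c(6, 6.3),
                      low = c(4, 4.3))
  mr <- match_ratings(pain, other)
  expect_equal(mr$pairs$other_id, "t1")
  expect_equal(mr$pairs$err_high + mr$pairs$err_low, 0)
})

test_that("matched pairs are injective and within tolerance on a synthetic cohort", {
  cfg <- generator_config(n_subjects = 200, seed = 1)
  rat <- generate_multimodal_ratings(cfg, c("pain", "touch"),
                                     offsets = c(0, 1))
  mr <- match_ratings(rating_means(rat, "pain"), rating_means(rat, "touch"),
                      tol = 0.5, seed = 1)
  expect_gt(nrow(mr$pairs), 50)
  expect_true(all(mr$pairs$err_high <= 0.5 + 1e-12))
  expect_true(all(mr$pairs$err_low <= 0.5 + 1e-12))
  expect_false(any(duplicated(mr$pairs$pain_id)))
  expect_false(any(duplicated(mr$pairs$other_id)))
  # seeded determinism is bit-exact
  mr2 <- match_ratings(rating_means(rat, "pain"), rating_means(rat, "touch"),
                       tol = 0.5, seed = 1)
  expect_identical(mr$pairs, mr2$pairs)
  expect_error(match_ratings(rating_means(rat, "pain")[0, ],
                             rating_means(rat, "touch")), "empty")
})

test_that("matching equates between-modality mean ratings", {
  gaps_ok <- 0
  t_ok <- 0
  for (s in 1:10) {
    # low base keeps high-intensity ratings clear of the 10-point scale end
    cfg <- generator_config(n_subjects = 120, rating_base_mean = 3,
                            seed = 300 + s)
    rat <- generate_multimodal_ratings(cfg, c("pain", "audition"),
                                       offsets = c(0, 2))
    pm <- rating_means(rat, "pain"); am <- rating_means(rat, "audition")
    mr <- match_ratings(pm, am, tol = 0.5, seed = s)
    if (nrow(mr$pairs) < 10) next
    hp <- pm$high[match(mr$pairs$pain_id, pm$subject_id)]
    ha <- am$high[match(mr$pairs$other_id, am$subject_id)]
    lp <- pm$low[match(mr$pairs$pain_id, pm$subject_id)]
    la <- am$low[match(mr$pairs$other_id, am$subject_id)]
    gaps_ok <- gaps_ok + (abs(mean(hp - ha)) < 0.5 && abs(mean(lp - la)) < 0.5)
    # matched groups are indistinguishable in mean rating difference
    p <- t.test(hp - lp, ha - la)$p.value
    t_ok <- t_ok + (p > 0.05)
  }
  expect_gte(gaps_ok, 9)
  expect_gte(t_ok, 9)
})

test_that("matched contrasts separate preferential from shared coupling", {
  pref <- 0; null_ok <- 0
  for (s in 1:5) {
    base <- list(n_subjects = 40, n_trials_per_condition = 8)
    cfg_pain <- do.call(generator_config, c(base, list(
      rho_var_discrim = 0.7, seed = 400 + s)))
    # other modality: no variability-discriminability coupling
    cfg_none <- do.call(generator_config, c(base, list(
      rho_var_discrim = 0, rho_amp_discrim = 0, seed = 500 + s)))
    make <- function(cfg) {
      sim <- generate_cohort(cfg)
      list(tracks = cohort_diff_tracks(sim$epochs, "tempSD", step_ms = 10),
           cov = cohort_diff_tracks(sim$epochs, "amplitude", step_ms = 10),
           scores = discrim_scores(sim$ratings),
           means = rating_means(sim$ratings, "pain"))
    }
    pain <- make(cfg_pain); other <- make(cfg_none)
    mr <- match_ratings(pain$means, other$means, tol = 1.5, seed = s)
    if (nrow(mr$pairs) < 10) next
    res <- matched_contrast(mr, pain, other, min_pairs = 10)
    pref <- pref + (res$pain$p < 0.05 && res$other$bf < 1)
    # shared coupling: no significant difference expected
    other2 <- make(do.call(generator_config, c(base, list(seed = 600 + s))))
    mr2 <- match_ratings(pain$means, other2$means, tol = 1.5, seed = s)
    if (nrow(mr2$pairs) >= 10) {
      res2 <- matched_contrast(mr2, pain, other2, min_pairs = 10)
      null_ok <- null_ok + (res2$diff$p > 0.05)
    }
  }
  expect_gte(pref, 4)
  expect_gte(null_ok, 4)
})

test_that("degenerate matched contrasts are rejected", {
  mr <- structure(list(pairs = data.frame(pain_id = character(),
                                          other_id = character(),
                                          err_high = numeric(),
                                          err_low = numeric()),
                       unmatched = character(), tol = 0.5),
                  class = "match_result")
  expect_error(matched_contrast(mr, list(), list()), "empty match")
})
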