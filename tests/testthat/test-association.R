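test_that("a planted cohort yields a significant post-stimulus cluster", {
  mt <- mid_tracks()
  tr <- track_association(mt$dvar, mt$scores, covariate_tracks = mt$damp,
                          compute_bf = FALSE)
  expect_s3_class(tr, "association_track")
  expect_false(any(tr$q_sig[tr$times < 0]))   # FDR family is post-stimulus
  sig_in_window <- tr$q_sig[tr$times >= 150 & tr$times <= 450]
  expect_gt(mean(sig_in_window), 0.5)
  roi <- roi_association(mt$dvar, mt$scores, covariate_tracks = mt$damp)
  expect_gt(roi$r, 0.2)
  expect_lt(roi$p, 0.01)
  expect_gt(roi$bf, 3.3)
})

test_that("shuffled scores yield no FDR-significant points in most seeds", {
  mt <- mid_tracks()
  set.seed(909)
  clean <- 0
  for (i in 1:20) {
    sc <- mt$scores
    sc$value <- sample(sc$value)
    tr <- track_association(mt$dvar, sc, covariate_tracks = mt$damp,
                            compute_bf = FALSE)
    clean <- clean + (sum(tr$q_sig) == 0)
  }
  expect_gte(clean, 18)
})

test_that("partialling a track on itself gives zero everywhere", {
  mt <- mid_tracks()
  tr <- track_association(mt$dvar, mt$scores, covariate_tracks = mt$dvar,
                          compute_bf = FALSE)
  expect_lt(max(abs(tr$r)), 1e-6)
  expect_false(any(tr$q_sig))
})

test_that("track correlations agree with per-point reference computations", {
  mt <- mid_tracks()
  idx <- c(200, 700, 1200)
  tr_plain <- track_association(mt$dvar, mt$scores, compute_bf = FALSE)
  tr_part <- track_association(mt$dvar, mt$scores,
                               covariate_tracks = mt$damp, compute_bf = FALSE)
  y <- mt$scores$value[match(rownames(mt$dvar$delta), mt$scores$subject_id)]
  for (j in idx) {
    ref <- pearson_corr(mt$dvar$delta[, j], y)
    expect_equal(tr_plain$r[j], ref$r, tolerance = 1e-12)
    expect_equal(tr_plain$p[j], ref$p, tolerance = 1e-12)
    refp <- partial_corr(mt$dvar$delta[, j], y, mt$damp$delta[, j])
    expect_equal(tr_part$r[j], refp$r, tolerance = 1e-12)
    expect_equal(tr_part$p[j], refp$p, tolerance = 1e-12)
  }
  # spearman variant is rank-based
  tr_s <- track_association(mt$dvar, mt$scores, method = "spearman",
                            compute_bf = FALSE)
  ref_s <- cor(rank(mt$dvar$delta[, 700]), rank(y))
  expect_equal(tr_s$r[700], ref_s, tolerance = 1e-12)
})

test_that("intra-individual analysis recovers a trial-level coupling", {
  # ratings driven by each trial's own ROI variability plus noise
  sim <- small_cohort()
  ratings <- sim$ratings
  for (e in sim$epochs) {
    tr <- sliding_track(e, "tempSD", step_ms = 25)
    roi_v <- rowMeans(tr$values[, tr$times >= 250 & tr$times <= 350])
    occ <- stats::ave(seq_along(e$condition), e$condition, FUN = seq_along)
    key_e <- paste(e$subject_id, e$condition, occ)
    key_r <- paste(ratings$subject_id, ratings$condition, ratings$trial_index)
    m <- match(key_e, key_r)
    set.seed(sum(m))
    ratings$rating[m] <- pmin(pmax(2 * roi_v + rnorm(length(m), 0, 0.3),
                                   0), 10)
  }
  res <- intra_individual(sim$epochs, ratings, step_ms = 25)
  eff <- res$times >= 250 & res$times <= 350
  expect_gt(mean(res$t[eff]), 2)
  expect_true(any(res$q_sig[eff]))
  # independent ratings: mostly clean tracks
  set.seed(4242)
  clean <- 0
  for (i in 1:10) {
    rat2 <- sim$ratings
    rat2$rating <- sample(rat2$rating)
    r2 <- intra_individual(sim$epochs, rat2, step_ms = 25)
    clean <- clean + (sum(r2$q_sig) == 0)
  }
  expect_gte(clean, 9)
})

test_that("sensitivity analysis is null without a planted sensitivity link", {
  sim <- mid_cohort()
  sa <- sensitivity_analysis(sim$epochs, sim$ratings, step_ms = 25,
                             compute_bf = FALSE)
  expect_lt(sum(sa$q_sig), 3)
})

test_that("sensitivity analysis detects a planted sensitivity coupling", {
  # make mean ratings track each subject's pooled ROI variability
  sim <- mid_cohort()
  pooled <- vapply(sim$epochs, function(e) {
    tr <- sliding_track(e, "tempSD", step_ms = 25)
    mean(colMeans(tr$values)[tr$times >= 250 & tr$times <= 350])
  }, 0)
  ratings <- sim$ratings
  set.seed(31)
  shift <- 2.5 * (pooled - mean(pooled)) / sd(pooled)
  for (i in seq_along(sim$epochs)) {
    id <- sim$epochs[[i]]$subject_id
    sel <- ratings$subject_id == id
    ratings$rating[sel] <- pmin(pmax(ratings$rating[sel] + shift[i], 0), 10)
  }
  sa <- sensitivity_analysis(sim$epochs, ratings, step_ms = 25,
                             compute_bf = FALSE)
  eff <- sa$times >= 200 & sa$times <= 400   # 9 window centers at step 25
  expect_gte(sum(sa$q_sig[eff]), 5)
  expect_error(sensitivity_analysis(sim$epochs[1:2], sim$ratings),
               "at least 4")
})

test_that("subject mismatches are rejected", {
  mt <- mid_tracks()
  bad <- mt$scores
  bad$subject_id[1] <- "zz"
  expect_error(track_association(mt$dvar, bad, compute_bf = FALSE),
               "do not match")
})
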