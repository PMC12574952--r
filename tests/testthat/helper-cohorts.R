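# Shared small fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

# small full-geometry cohort with planted defaults
small_cohort <- function() cached("small", generate_cohort(
  generator_config(n_subjects = 12, n_trials_per_condition = 8, seed = 42)))

# moderate cohort for association/dominance/robustness checks
mid_cohort <- function() cached("mid", generate_cohort(
  generator_config(n_subjects = 40, n_trials_per_condition = 10, seed = 7)))

mid_tracks <- function() cached("mid_tracks", {
  sim <- mid_cohort()
  list(dvar = cohort_diff_tracks(sim$epochs, "tempSD"),
       damp = cohort_diff_tracks(sim$epochs, "amplitude"),
       scores = discrim_scores(sim$ratings))
})

# compact epoch geometry for Monte-Carlo loops (shorter epoch, lower sfreq)
fast_config <- function(...) {
  generator_config(sfreq = 250, epoch_window = c(-200, 600), ...)
}

# two-pass reference SD (oracle): mean first, then squared deviations
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

# exhaustive permutation-entropy oracle over explicit embedding vectors
pe_enumerate <- function(x, m, tau) {
  nv <- length(x) - (m - 1) * tau
  pats <- character(nv)
  for (t in seq_len(nv)) {
    v <- x[t + (0:(m - 1)) * tau]
    pats[t] <- paste(rank(v, ties.method = "first"), collapse = "-")
  }
  p <- table(pats) / nv
  -sum(p * log(p))
}

# brute-force Benjamini-Hochberg: largest k with p_(k) <= k * alpha / m
bh_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  sig <- rep(FALSE, m)
  if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
  sig
}
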