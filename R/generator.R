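#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a single-channel (Cz) pain-EEG study: 1,500-sample
#' epochs (-500..+999 ms at 1 kHz), a biphasic evoked template with an
#' N2-like negative deflection near 200 ms and a P2-like positive
#' deflection near 400 ms whose amplitude is larger for high-intensity
#' stimuli, an induced (trial-random-phase, average-cancelling) broadband
#' component whose high-minus-low gain varies across subjects, 1-30 Hz
#' background noise present throughout the epoch, and 0-10 NRS ratings from
#' a per-subject offset plus a per-subject high-minus-low difference plus
#' trial noise.
#'
#' @param n_subjects subjects per cohort.
#' @param n_trials_per_condition trials per intensity condition (15, the
#'   per-condition trial count of the emulated designs).
#' @param sfreq sampling rate, Hz.
#' @param epoch_window epoch span in ms, \code{c(from, to)}; samples run
#'   from \code{from} to \code{to - 1000 / sfreq} so the default gives
#'   1,500 samples with t = 0 at stimulus onset.
#' @param conditions ordered intensity labels, low to high.
#' @param erp_peak_latencies ms latencies of the negative and positive
#'   template deflections.
#' @param erp_amp evoked template scale, microvolts (N2-like depth).
#' @param amp_effect multiplicative gain of the high condition on evoked
#'   amplitude (1 = no amplitude effect).
#' @param amp_gain_sd across-subject SD of that gain.
#' @param sigma_base baseline induced-component SD, microvolts.
#' @param var_effect_mean,var_effect_sd across-subject mean and SD of the
#'   planted high-minus-low induced-variability gain (microvolts).
#' @param discrim_mean,discrim_sd across-subject mean and SD of the planted
#'   rating difference (NRS units).
#' @param rho_var_discrim planted correlation between the per-subject
#'   variability gain and rating difference.
#' @param rho_amp_discrim planted correlation between the per-subject
#'   amplitude gain and rating difference.
#' @param rating_base_mean,rating_base_sd across-subject distribution of
#'   the low-condition mean rating (NRS units).
#' @param rating_noise_sd within-subject trial rating SD (NRS units).
#' @param noise_sd background-noise SD, microvolts.
#' @param noise_band background-noise band, Hz (matches the 1-30 Hz
#'   analysis filter).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   cohort bit-exactly.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_subjects = 30,
                             n_trials_per_condition = 15,
                             sfreq = 1000,
                             epoch_window = c(-500, 1000),
                             conditions = c("low", "high"),
                             erp_peak_latencies = c(200, 400),
                             erp_amp = 6,
                             amp_effect = 1.3,
                             amp_gain_sd = 0.15,
                             sigma_base = 2,
                             var_effect_mean = 1.5,
                             var_effect_sd = 1.5,
                             discrim_mean = 2,
                             discrim_sd = 1,
                             rho_var_discrim = 0.5,
                             rho_amp_discrim = 0.3,
                             rating_base_mean = 4,
                             rating_base_sd = 1,
                             rating_noise_sd = 0.8,
                             noise_sd = 1.2,
                             noise_band = c(1, 30),
                             seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1 || cfg$n_trials_per_condition < 1)
    stop("subject and trial counts must be positive")
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0))
    stop("epoch_window must span stimulus onset (t = 0)")
  if (length(conditions) < 2L) stop("need at least two intensity conditions")
  sds <- c(amp_gain_sd, var_effect_sd, discrim_sd, rating_base_sd,
           rating_noise_sd, noise_sd, sigma_base)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  if (abs(rho_var_discrim) > 1 || abs(rho_amp_discrim) > 1)
    stop("planted correlations must lie in [-1, 1]")
  structure(cfg, class = "generator_config")
}

#' Evoked-response template
#'
#' Biphasic unit template: a negative Gaussian-windowed deflection (width
#' 45 ms) at the first latency and a positive one (width 55 ms, 4/3 the
#' depth) at the second, zero before stimulus onset.
#'
#' @param times ms time axis.
#' @param latencies ms latencies of the two deflections.
#' @return Numeric vector, unit negative-peak depth.
#' @export
erp_template <- function(times, latencies = c(200, 400)) {
  tpl <- -exp(-0.5 * ((times - latencies[1]) / 45)^2) +
    (4 / 3) * exp(-0.5 * ((times - latencies[2]) / 55)^2)
  tpl[times < 0] <- 0
  tpl
}

# post-stimulus envelope of the induced component: zero pre-stimulus,
# Gaussian bump centred 300 ms after onset
induced_envelope <- function(times) {
  g <- exp(-0.5 * ((times - 300) / 150)^2)
  g[times < 0] <- 0
  g
}

# band-limited Gaussian noise, n_trials x n_time, built in the frequency
# domain (random complex coefficients inside the band, Hermitian spectrum),
# each row normalised to unit population SD => trial phases are random and
# the trial average cancels
band_noise <- function(n_trials, n_time, sfreq, band) {
  freqs <- (0:(n_time - 1)) * sfreq / n_time
  half <- freqs[2:ceiling(n_time / 2)]
  keep <- which(half >= band[1] & half <= band[2])
  if (!length(keep)) stop("noise band contains no resolvable frequency")
  spec <- matrix(0 + 0i, n_time, n_trials)
  z <- matrix(complex(real = stats::rnorm(length(keep) * n_trials),
                      imaginary = stats::rnorm(length(keep) * n_trials)),
              length(keep), n_trials)
  spec[1 + keep, ] <- z
  spec[n_time + 1 - keep, ] <- Conj(z)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_time
  x <- t(x)
  sds <- sqrt(rowMeans(x^2) - rowMeans(x)^2)
  x / sds
}

# per-subject latent draws realising the planted correlation structure:
# D (rating difference), dsig (variability gain) and gam (amplitude gain)
# all load on a shared standard-normal factor via their rho with D
draw_subject_params <- function(cfg) {
  n <- cfg$n_subjects
  dz <- stats::rnorm(n)
  vz <- cfg$rho_var_discrim * dz +
    sqrt(1 - cfg$rho_var_discrim^2) * stats::rnorm(n)
  az <- cfg$rho_amp_discrim * dz +
    sqrt(1 - cfg$rho_amp_discrim^2) * stats::rnorm(n)
  D <- cfg$discrim_mean + cfg$discrim_sd * dz
  dsig <- cfg$var_effect_mean + cfg$var_effect_sd * vz
  clipped <- sum(dsig < -cfg$sigma_base)
  dsig <- pmax(dsig, -cfg$sigma_base)   # induced SD cannot go negative
  gam <- (cfg$amp_effect - 1) + cfg$amp_gain_sd * az
  mu <- cfg$rating_base_mean + cfg$rating_base_sd * stats::rnorm(n)
  list(D = D, dsig = dsig, gam = gam, mu = mu, n_sigma_clipped = clipped)
}

#' Generate a synthetic multi-subject cohort with planted effects
#'
#' Simulates epoched EEG and trial ratings under a known ground truth. Per
#' subject i, condition c and trial k the signal is
#' \deqn{x(t) = a_{i,c} ERP(t) + (\sigma_b + [c = high] \Delta\sigma_i)
#'   g(t) w_k(t) + \epsilon_k(t)}
#' with \code{ERP} the biphasic template, \code{g} a post-stimulus
#' envelope, \code{w_k} unit-SD band-limited noise with trial-random phase
#' (so its trial average cancels) and \code{eps_k} background noise present
#' in baseline and post-stimulus alike. Ratings are
#' \code{mu_i + [c = high] D_i + eta}, \code{eta ~ N(0, rating_noise_sd)},
#' clipped to the 0-10 NRS (clip count recorded in the ground truth).
#'
#' @param cfg a [generator_config()].
#' @return list with \code{epochs} (list of \code{epoch_set}),
#'   \code{ratings} (data.frame) and \code{truth} (data.frame of planted
#'   per-subject parameters; attributes \code{realized_rho_var},
#'   \code{realized_rho_amp}, \code{n_ratings_clipped},
#'   \code{n_sigma_clipped}).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  dt <- 1000 / cfg$sfreq
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2] - dt, by = dt)
  tpl <- erp_template(times, cfg$erp_peak_latencies) * cfg$erp_amp
  env <- induced_envelope(times)
  pars <- draw_subject_params(cfg)
  ntr <- cfg$n_trials_per_condition
  conds <- cfg$conditions
  high_label <- conds[length(conds)]
  ids <- sprintf("s%03d", seq_len(cfg$n_subjects))
  epochs <- vector("list", cfg$n_subjects)
  names(epochs) <- ids
  rat <- vector("list", cfg$n_subjects)
  nclip <- 0L
  for (i in seq_len(cfg$n_subjects)) {
    cond <- rep(conds, each = ntr)
    ishigh <- cond == high_label
    amp <- 1 + pars$gam[i] * ishigh   # per-trial evoked gain
    sig <- cfg$sigma_base + pars$dsig[i] * ishigh
    osc <- band_noise(length(cond), length(times), cfg$sfreq, cfg$noise_band)
    eps <- cfg$noise_sd *
      band_noise(length(cond), length(times), cfg$sfreq, cfg$noise_band)
    x <- tcrossprod(amp, tpl) +
      (sig * osc) * matrix(env, length(cond), length(times), byrow = TRUE) +
      eps
    epochs[[i]] <- epoch_set(x, times, cond, subject_id = ids[i],
                             sfreq = cfg$sfreq, modality = "pain")
    r <- pars$mu[i] + pars$D[i] * ishigh +
      stats::rnorm(length(cond), 0, cfg$rating_noise_sd)
    nclip <- nclip + sum(r < 0 | r > 10)
    rat[[i]] <- data.frame(subject_id = ids[i], modality = "pain",
                           condition = cond,
                           trial_index = stats::ave(seq_along(cond), cond,
                                                    FUN = seq_along),
                           rating = pmin(pmax(r, 0), 10))
  }
  ratings <- do.call(rbind, rat)
  rownames(ratings) <- NULL
  truth <- data.frame(subject_id = ids, D = pars$D, delta_sigma = pars$dsig,
                      amp_gain = pars$gam, mu = pars$mu)
  safe_cor <- function(a, b)
    if (isTRUE(stats::sd(a) > 0 && stats::sd(b) > 0)) stats::cor(a, b)
    else NA_real_
  attr(truth, "realized_rho_var") <- safe_cor(pars$dsig, pars$D)
  attr(truth, "realized_rho_amp") <- safe_cor(pars$gam, pars$D)
  attr(truth, "n_ratings_clipped") <- nclip
  attr(truth, "n_sigma_clipped") <- pars$n_sigma_clipped
  list(epochs = epochs, ratings = ratings, truth = truth)
}

#' Generate ratings for several modalities
#'
#' Applies the cohort rating model independently per modality with a
#' modality-specific shift of the low-condition mean rating; used to
#' exercise the cross-modality rating-matching procedure.
#'
#' @param cfg a [generator_config()] (rating parameters and seed are used).
#' @param modalities character vector of modality labels (nonempty).
#' @param offsets numeric per-modality shifts of the mean rating (recycled
#'   if length 1); must be finite.
#' @param discrim_means optional per-modality mean planted rating
#'   difference (defaults to \code{cfg$discrim_mean} for all).
#' @return Ratings data.frame with one block per modality.
#' @export
generate_multimodal_ratings <- function(cfg, modalities, offsets = 0,
                                        discrim_means = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!length(modalities)) stop("empty modality list")
  if (anyDuplicated(modalities)) stop("duplicate modality labels")
  offsets <- rep_len(offsets, length(modalities))
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  if (is.null(discrim_means))
    discrim_means <- rep(cfg$discrim_mean, length(modalities))
  discrim_means <- rep_len(discrim_means, length(modalities))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  ntr <- cfg$n_trials_per_condition
  conds <- cfg$conditions
  high_label <- conds[length(conds)]
  ids <- sprintf("s%03d", seq_len(cfg$n_subjects))
  out <- list()
  for (j in seq_along(modalities)) {
    mu <- cfg$rating_base_mean + offsets[j] +
      cfg$rating_base_sd * stats::rnorm(cfg$n_subjects)
    D <- discrim_means[j] + cfg$discrim_sd * stats::rnorm(cfg$n_subjects)
    for (i in seq_len(cfg$n_subjects)) {
      cond <- rep(conds, each = ntr)
      r <- mu[i] + D[i] * (cond == high_label) +
        stats::rnorm(length(cond), 0, cfg$rating_noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = ids[i], modality = modalities[j], condition = cond,
        trial_index = stats::ave(seq_along(cond), cond, FUN = seq_along),
        rating = pmin(pmax(r, 0), 10))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subject condition-mean ratings
#'
#' @param ratings ratings data.frame.
#' @param modality modality to summarise.
#' @param high,low condition labels.
#' @return data.frame (subject_id, high, low) of mean ratings, ordered by
#'   subject id.
#' @export
rating_means <- function(ratings, modality, high = "high", low = "low") {
  r <- ratings[ratings$modality == modality, ]
  if (!nrow(r)) stop("no ratings for modality '", modality, "'")
  ids <- sort(unique(r$subject_id))
  data.frame(
    subject_id = ids,
    high = vapply(ids, function(id)
      mean(r$rating[r$subject_id == id & r$condition == high]), 0),
    low = vapply(ids, function(id)
      mean(r$rating[r$subject_id == id & r$condition == low]), 0),
    row.names = NULL)
}
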