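#' Noise-injection configuration
#'
#' @param scales noise scales (default 0 to 2 in steps of 0.2 - 11 values).
#' @param target which condition(s) receive noise: \code{"low"},
#'   \code{"high"} or \code{"both"}.
#' @param baseline_interval ms interval noise is sampled from (pre-stimulus).
#' @param seed integer seed.
#' @return A \code{noise_config} list.
#' @export
noise_config <- function(scales = seq(0, 2, by = 0.2),
                         target = c("both", "low", "high"),
                         baseline_interval = c(-500, 0), seed = 1) {
  target <- match.arg(target)
  if (any(scales < 0)) stop("noise scales must be >= 0")
  if (baseline_interval[2] > 0)
    stop("baseline interval must be pre-stimulus")
  structure(list(scales = scales, target = target,
                 baseline_interval = baseline_interval, seed = seed),
            class = "noise_config")
}

#' Inject baseline-sampled noise into post-stimulus EEG
#'
#' For every targeted trial a noise trace is assembled from the baseline
#' segments of randomly chosen trials of the same subject (drawn with
#' replacement, so the subject's own residual-noise structure is
#' respected), multiplied by \code{scale}, and added to the post-stimulus
#' samples only. The baseline (500 ms) is shorter than the post-stimulus
#' window (1,000 ms), so two independently drawn baseline segments are
#' concatenated and trimmed. Pre-stimulus samples are never touched and
#' \code{scale = 0} returns the input unchanged.
#'
#' @param e an \code{epoch_set}.
#' @param scale non-negative noise multiplier.
#' @param target \code{"low"}, \code{"high"} or \code{"both"}.
#' @param seed integer seed.
#' @param baseline_interval ms interval to sample noise from.
#' @return The perturbed \code{epoch_set}.
#' @export
inject_noise <- function(e, scale, target = "both", seed = 1,
                         baseline_interval = c(min(e$times), 0)) {
  stopifnot(inherits(e, "epoch_set"), scale >= 0)
  if (scale == 0) return(e)
  rows <- if (target == "both") seq_len(nrow(e$data))
  else which(e$condition == target)
  if (!length(rows)) stop("target condition '", target, "' absent")
  base_sel <- which(e$times >= baseline_interval[1] & e$times < baseline_interval[2])
  post_sel <- which(e$times >= 0)
  if (!length(base_sel)) stop("no baseline samples available")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nb <- length(base_sel); np <- length(post_sel)
  ndraw <- ceiling(np / nb)
  for (i in rows) {
    donors <- sample(nrow(e$data), ndraw, replace = TRUE)
    trace <- as.vector(t(e$data[donors, base_sel, drop = FALSE]))[seq_len(np)]
    e$data[i, post_sel] <- e$data[i, post_sel] + scale * trace
  }
  e
}

#' Noise-scale sweep of the ROI partial correlation
#'
#' Reruns the peak-ROI partial correlation between the variability
#' difference and discriminability (controlling for the amplitude
#' difference) after injecting baseline-sampled noise at each scale, and
#' reports the partial r, the JZS Bayes factor, and a support flag
#' (\code{log10(BF) >= 0.5}, i.e. BF >= 3.3 approx, "substantial").
#'
#' @param cohort list of \code{epoch_set}s.
#' @param scores per-subject discriminability ([discrim_scores()] frame or
#'   vector aligned with the cohort).
#' @param config a [noise_config()].
#' @param window_ms sliding-window length.
#' @return data.frame with one row per (scale, target): scale, target,
#'   partial_r, p, bf, log10_bf, supported.
#' @export
noise_sweep <- function(cohort, scores, config = noise_config(),
                        window_ms = 100) {
  stopifnot(inherits(config, "noise_config"))
  targets <- if (config$target == "both") "both" else config$target
  rows <- list()
  for (target in targets) for (k in seq_along(config$scales)) {
    sc <- config$scales[k]
    pert <- lapply(seq_along(cohort), function(i)
      inject_noise(cohort[[i]], sc,
                   target = if (target == "both") "both" else target,
                   seed = config$seed + 1000L * k + i,
                   baseline_interval = config$baseline_interval))
    dvar <- cohort_diff_tracks(pert, "tempSD", window_ms = window_ms)
    damp <- cohort_diff_tracks(pert, "amplitude", window_ms = window_ms)
    res <- roi_association(dvar, scores, covariate_tracks = damp)
    rows[[length(rows) + 1L]] <- data.frame(
      scale = sc, target = target, partial_r = res$r, p = res$p,
      bf = res$bf, log10_bf = log10(res$bf),
      supported = log10(res$bf) >= 0.5)
  }
  do.call(rbind, rows)
}

#' Bootstrap power map over subjects or trials
#'
#' Estimates, for each resample size, the probability that each
#' post-stimulus time point shows an FDR-significant correlation between
#' the high-minus-low metric track and discriminability. Resampling is
#' bootstrap (with replacement) along one axis: when resampling subjects
#' all trials are used, and when resampling trials all subjects are used.
#' Per-trial metric tracks are computed once and re-averaged per resample.
#'
#' @param cohort list of \code{epoch_set}s.
#' @param scores per-subject discriminability scores.
#' @param axis \code{"subjects"} or \code{"trials"}.
#' @param sizes resample sizes (subject counts, or trials per condition).
#' @param metric \code{"tempSD"} or \code{"amplitude"}.
#' @param n_reps bootstrap repetitions per size (default 100).
#' @param alpha FDR level.
#' @param seed integer seed.
#' @param window_ms sliding-window length.
#' @return A \code{power_map}: list with \code{axis}, \code{sizes},
#'   \code{times} (post-stimulus centers), \code{prob} (sizes x times
#'   matrix), \code{contour80} (prob >= 0.8).
#' @export
power_map <- function(cohort, scores, axis = c("subjects", "trials"),
                      sizes, metric = "tempSD", n_reps = 100, alpha = 0.05,
                      seed = 1, window_ms = 100) {
  axis <- match.arg(axis)
  if (is.data.frame(scores)) {
    m <- match(vapply(cohort, function(e) e$subject_id, ""),
               scores$subject_id)
    if (anyNA(m)) stop("subjects in cohort and scores do not match")
    scores <- scores$value[m]
  }
  ns <- length(cohort)
  pertrial <- lapply(cohort, sliding_track, metric = metric,
                     window_ms = window_ms)
  times <- pertrial[[1L]]$times
  conds <- lapply(pertrial, `[[`, "condition")
  ntr_min <- min(vapply(conds, function(cc) min(table(cc)), 0))
  if (axis == "subjects" && any(sizes > ns))
    stop("subject resample sizes exceed the cohort size")
  if (axis == "trials" && any(sizes > ntr_min))
    stop("trial resample sizes exceed the available trials per condition")
  delta_full <- do.call(rbind, lapply(pertrial, function(tr) {
    colMeans(tr$values[tr$condition == "high", , drop = FALSE]) -
      colMeans(tr$values[tr$condition == "low", , drop = FALSE])
  }))
  post <- times >= 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  prob <- matrix(0, length(sizes), sum(post),
                 dimnames = list(sizes, NULL))
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    hits <- numeric(sum(post))
    for (rep in seq_len(n_reps)) {
      if (axis == "subjects") {
        idx <- sample(ns, sz, replace = TRUE)
        D <- delta_full[idx, post, drop = FALSE]
        y <- scores[idx]
      } else {
        D <- do.call(rbind, lapply(seq_len(ns), function(i) {
          hi <- which(conds[[i]] == "high"); lo <- which(conds[[i]] == "low")
          hs <- sample(hi, sz, replace = TRUE)
          ls <- sample(lo, sz, replace = TRUE)
          colMeans(pertrial[[i]]$values[hs, post, drop = FALSE]) -
            colMeans(pertrial[[i]]$values[ls, post, drop = FALSE])
        }))
        y <- scores
      }
      sdy <- stats::sd(y)
      if (sdy == 0) next
      r <- col_corr(D, y)
      p <- corr_p(r, nrow(D) - 2)
      hits <- hits + fdr_bh(p, alpha)
    }
    prob[si, ] <- hits / n_reps
  }
  structure(list(axis = axis, sizes = sizes, times = times[post],
                 prob = prob, contour80 = prob >= 0.8),
            class = "power_map")
}

#' Smallest resample size reaching a detection probability
#'
#' @param map a [power_map()] result.
#' @param threshold probability threshold (default 0.8).
#' @return Numeric vector over time points: the smallest size whose
#'   probability meets the threshold, \code{NA} where never reached.
#' @export
min_size_for_power <- function(map, threshold = 0.8) {
  apply(map$prob, 2L, function(col) {
    i <- which(col >= threshold)
    if (length(i)) map$sizes[min(i)] else NA_real_
  })
}

#' @export
as.data.frame.power_map <- function(x, ...) {
  data.frame(size = rep(x$sizes, times = length(x$times)),
             time_ms = rep(x$times, each = length(x$sizes)),
             prob = as.vector(x$prob))
}
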