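#' Temporal standard deviation of a time window
#'
#' Moment-to-moment neural variability within a window: the square root of
#' the mean squared deviation from the window mean, with divisor \code{n}
#' (population form).
#'
#' @param x numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
temporal_sd <- function(x) {
  n <- length(x)
  if (n < 2L) stop("temporal_sd needs at least 2 samples")
  sqrt(sum((x - mean(x))^2) / n)
}

#' Coefficient of variation of a time window
#'
#' \code{temporal_sd(x) / mean(x)}. The CV is unstable when the window mean
#' is near zero (common in baseline-corrected EEG); in that case \code{Inf}
#' (signed by the SD, i.e. \code{+Inf}) is returned as a sentinel rather
#' than an error, and the metric should not be interpreted.
#'
#' @param x numeric vector, length >= 2.
#' @param tol relative tolerance below which the mean counts as zero.
#' @return Scalar, or \code{Inf} sentinel for a near-zero mean.
#' @export
coefficient_of_variation <- function(x, tol = 1e-12) {
  s <- temporal_sd(x)
  m <- mean(x)
  if (abs(m) <= tol * max(1, s)) return(Inf)
  s / m
}

# all permutations of 1..m in lexicographic order (m small)
perm_table <- function(m) {
  if (m == 1L) return(matrix(1L, 1L))
  sub <- perm_table(m - 1L)
  out <- matrix(0L, 0L, m)
  for (first in seq_len(m)) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

#' Ordinal patterns of a time series
#'
#' Extracts the \code{n - (m - 1) * tau} delay-embedding vectors of a
#' series and codes each by the ordinal (rank) pattern of its elements.
#' Ties are ranked by order of appearance (stable), so integer-valued test
#' signals are handled deterministically; for real EEG exact ties have
#' measure zero.
#'
#' @param x numeric vector.
#' @param m embedding dimension (>= 2).
#' @param tau delay in samples.
#' @return Integer vector of pattern codes in \code{1..factorial(m)}
#'   (lexicographic rank-pattern index).
#' @export
ordinal_patterns <- function(x, m = 4, tau = 1) {
  n <- length(x)
  if (m < 2L) stop("embedding dimension m must be >= 2")
  nv <- n - (m - 1L) * tau
  if (nv < 1L) stop("series too short: need length >= (m-1)*tau + 1")
  emb <- vapply(seq_len(m), function(j) x[seq_len(nv) + (j - 1L) * tau],
                numeric(nv))
  if (nv == 1L) emb <- matrix(emb, 1L)
  ranks <- t(apply(emb, 1L, rank, ties.method = "first"))
  # lexicographic index of the rank vector via the factorial number system
  code <- rep(1L, nv)
  fact <- factorial(m)
  for (j in seq_len(m - 1L)) {
    smaller_after <- rowSums(ranks[, (j + 1L):m, drop = FALSE] <
                               ranks[, j])
    fact <- fact / (m - j + 1L)
    code <- code + smaller_after * fact
  }
  as.integer(code)
}

#' Permutation entropy of a time window
#'
#' Shannon entropy (natural log) of the relative-frequency distribution of
#' ordinal patterns of length-\code{m} embedding vectors. Amplitude-blind:
#' invariant to strictly increasing transforms of the signal. Maximum is
#' \code{log(factorial(m))}.
#'
#' @inheritParams ordinal_patterns
#' @return Scalar in \code{[0, log(factorial(m))]}.
#' @export
permutation_entropy <- function(x, m = 4, tau = 1) {
  codes <- ordinal_patterns(x, m, tau)
  p <- tabulate(codes, nbins = factorial(m))
  p <- p[p > 0] / length(codes)
  -sum(p * log(p))
}

roll_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):length(cs)] - cs[seq_len(length(x) - w + 1L)]) / w
}

roll_sd_pop <- function(x, w) {
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x * x))
  n <- length(x)
  i <- seq_len(n - w + 1L)
  s1 <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  sqrt(pmax(s2 / w - (s1 / w)^2, 0))
}

roll_pe <- function(x, w, m, tau) {
  codes <- ordinal_patterns(x, m, tau)
  span <- (m - 1L) * tau            # embedding vectors per window: w - span
  k <- w - span
  if (k < 1L) stop("window too short for the embedding")
  nbin <- factorial(m)
  nwin <- length(x) - w + 1L
  out <- numeric(nwin)
  counts <- tabulate(codes[seq_len(k)], nbins = nbin)
  ent <- function(ct) {
    p <- ct[ct > 0] / k
    -sum(p * log(p))
  }
  out[1L] <- ent(counts)
  if (nwin > 1L) for (i in 2:nwin) {
    counts[codes[i - 1L]] <- counts[codes[i - 1L]] - 1L
    counts[codes[i + k - 1L]] <- counts[codes[i + k - 1L]] + 1L
    out[i] <- ent(counts)
  }
  out
}

#' Sliding-window metric tracks for every trial
#'
#' Evaluates a variability (or amplitude) metric in every full window of
#' each trial. Windows are full only (no padding) and time stamps refer to
#' window centers, so a track spans
#' \code{[t_start + w/2, t_end - w/2]}. The \code{"amplitude"} metric is the
#' window mean, the windowed ERP-amplitude companion measure.
#'
#' @param e an \code{epoch_set}.
#' @param metric one of \code{"tempSD"}, \code{"PE"}, \code{"CV"},
#'   \code{"amplitude"}.
#' @param window_ms window length in ms (default 100).
#' @param step_ms step between window starts in ms (default 1).
#' @param m,tau permutation-entropy embedding parameters (used for
#'   \code{metric = "PE"}).
#' @return A \code{metric_track}: list with \code{subject_id},
#'   \code{metric}, \code{condition} (per-trial labels), \code{window_ms},
#'   \code{step_ms}, \code{times} (window centers, ms) and \code{values}
#'   (trials x windows matrix).
#' @export
sliding_track <- function(e, metric = c("tempSD", "PE", "CV", "amplitude"),
                          window_ms = 100, step_ms = 1, m = 4, tau = 1) {
  stopifnot(inherits(e, "epoch_set"))
  metric <- match.arg(metric)
  w <- as.integer(round(window_ms * e$sfreq / 1000))
  s <- as.integer(round(step_ms * e$sfreq / 1000))
  n <- ncol(e$data)
  if (w > n) stop("window longer than the epoch")
  if (w < 2L || s < 1L) stop("window must span >= 2 samples and step >= 1")
  starts <- seq(1L, n - w + 1L, by = s)
  centers <- (e$times[starts] + e$times[starts + w - 1L]) / 2
  fullrow <- switch(metric,
    tempSD = function(x) roll_sd_pop(x, w),
    amplitude = function(x) roll_mean(x, w),
    PE = function(x) roll_pe(x, w, m, tau),
    CV = function(x) {
      mu <- roll_mean(x, w); sd <- roll_sd_pop(x, w)
      ifelse(abs(mu) <= 1e-12 * pmax(1, sd), Inf, sd / mu)
    })
  vals <- t(apply(e$data, 1L, fullrow))[, starts, drop = FALSE]
  structure(list(subject_id = e$subject_id, metric = metric,
                 condition = e$condition, window_ms = window_ms,
                 step_ms = step_ms, times = centers, values = vals),
            class = "metric_track")
}

#' @export
print.metric_track <- function(x, ...) {
  cat(sprintf("<metric_track> %s subject %s: %d row(s) x %d windows (%g ms, step %g ms)\n",
              x$metric, x$subject_id, nrow(x$values), ncol(x$values),
              x$window_ms, x$step_ms))
  invisible(x)
}

same_geometry <- function(a, b) {
  a$metric == b$metric && a$window_ms == b$window_ms &&
    a$step_ms == b$step_ms && length(a$times) == length(b$times) &&
    isTRUE(all.equal(a$times, b$times, tolerance = 1e-9))
}

#' Trial-average a track within one condition
#'
#' @param tracks a per-trial \code{metric_track} (from [sliding_track()]).
#' @param condition condition label to average over.
#' @return A single-row \code{metric_track} with \code{condition} set.
#' @export
condition_average <- function(tracks, condition) {
  idx <- which(tracks$condition == condition)
  if (!length(idx)) stop("no trials with condition '", condition, "'")
  tracks$values <- matrix(colMeans(tracks$values[idx, , drop = FALSE]), 1L)
  tracks$condition <- condition
  tracks
}

#' High-minus-low difference of two trial-averaged tracks
#'
#' @param high,low single-row \code{metric_track}s with identical geometry.
#' @return A \code{metric_track} with \code{condition = "diff"}.
#' @export
diff_track <- function(high, low) {
  if (!same_geometry(high, low))
    stop("tracks differ in metric or window geometry")
  high$values <- high$values - low$values
  high$condition <- "diff"
  high
}

#' Per-subject high-minus-low track matrix for a cohort
#'
#' Convenience wrapper: computes the trial-averaged high-minus-low track for
#' each subject and stacks them into a subjects x windows matrix.
#'
#' @param cohort list of \code{epoch_set}s.
#' @param metric metric name passed to [sliding_track()].
#' @param high,low condition labels.
#' @param ... further arguments to [sliding_track()].
#' @return list with \code{times}, \code{delta} (subjects x windows matrix,
#'   rownames = subject ids) and \code{mean} (subject-average track).
#' @export
cohort_diff_tracks <- function(cohort, metric = "tempSD", high = "high",
                               low = "low", ...) {
  rows <- lapply(cohort, function(e) {
    tr <- sliding_track(e, metric, ...)
    diff_track(condition_average(tr, high), condition_average(tr, low))
  })
  delta <- do.call(rbind, lapply(rows, function(t) t$values[1L, ]))
  rownames(delta) <- vapply(cohort, function(e) e$subject_id, "")
  list(times = rows[[1L]]$times, delta = delta, mean = colMeans(delta))
}

#' Peak region of interest of a subject-averaged track
#'
#' Locates the extremum of the subject-averaged difference track among
#' post-stimulus window centers and returns the interval
#' \code{peak +/- halfwidth_ms} (21 samples at 1 kHz with the default
#' half-width of 10 ms). Variability (SD) differences use the maximum;
#' permutation-entropy differences use the trough (\code{mode = "min"}).
#' An all-equal track has no unique extremum; the first is taken with a
#' warning.
#'
#' @param track a single-row \code{metric_track} (e.g. a subject-mean
#'   difference), or a list with \code{times} and \code{values}.
#' @param halfwidth_ms half-width of the interval in ms.
#' @param mode \code{"max"} (default) or \code{"min"}.
#' @param post_only restrict the search to centers at or after stimulus
#'   onset (default TRUE).
#' @return Numeric length-2 interval in ms (attribute \code{peak_ms}).
#' @export
peak_roi <- function(track, halfwidth_ms = 10, mode = c("max", "min"),
                     post_only = TRUE) {
  mode <- match.arg(mode)
  times <- track$times
  vals <- if (is.matrix(track$values)) track$values[1L, ] else track$values
  if (!length(vals)) stop("empty track")
  sel <- if (post_only) times >= 0 else rep(TRUE, length(times))
  v <- vals[sel]; t <- times[sel]
  if (length(unique(v)) == 1L)
    warning("track is constant over the search window; using its first point")
  i <- if (mode == "max") which.max(v) else which.min(v)
  peak <- t[i]
  structure(c(peak - halfwidth_ms, peak + halfwidth_ms), peak_ms = peak)
}

#' Mean track value over a time interval
#'
#' @param track a \code{metric_track} (single- or multi-row) or a list with
#'   \code{times}/\code{values}; for matrices the ROI mean is returned per
#'   row.
#' @param interval length-2 ms interval (e.g. from [peak_roi()]).
#' @return Scalar (or per-row vector) mean over window centers inside the
#'   interval (inclusive).
#' @export
roi_value <- function(track, interval) {
  stopifnot(length(interval) == 2L)
  sel <- track$times >= interval[1] - 1e-9 & track$times <= interval[2] + 1e-9
  if (!any(sel)) stop("interval contains no window centers")
  v <- track$values
  if (is.matrix(v)) rowMeans(v[, sel, drop = FALSE]) else mean(v[sel])
}
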