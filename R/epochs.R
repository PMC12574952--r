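#' Epoched single-channel EEG for one subject
#'
#' Container for one subject's epoched EEG at one channel: a trials x time
#' matrix in microvolts, a uniform time axis in milliseconds with t = 0 at
#' stimulus onset, and per-trial condition and modality labels.
#'
#' @param data numeric matrix, trials x time (microvolts).
#' @param times numeric vector of time stamps in ms; must be strictly
#'   increasing with a uniform step of \code{1000 / sfreq} and span stimulus
#'   onset (contain both negative and non-negative times).
#' @param condition character vector of per-trial intensity labels (one per
#'   row of \code{data}), e.g. \code{"low"} / \code{"high"}.
#' @param subject_id subject identifier.
#' @param sfreq sampling rate in Hz.
#' @param channel channel name; the analyses here are single-channel
#'   (vertex electrode by default).
#' @param modality per-trial stimulus modality label; recycled if length 1.
#' @return An object of class \code{epoch_set}.
#' @examples
#' e <- epoch_set(matrix(rnorm(20), 2), times = seq(-5, 4), condition = c("low", "high"),
#'                sfreq = 1000)
#' n_trials(e)
#' @export
epoch_set <- function(data, times, condition, subject_id = "s01",
                      sfreq = 1000, channel = "Cz", modality = "pain") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  times <- as.numeric(times)
  if (ncol(data) != length(times))
    stop("`data` must have one column per time stamp (", length(times),
         " expected, got ", ncol(data), ")")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  steps <- diff(times)
  if (max(steps) - min(steps) > 1e-6 * mean(steps))
    stop("`times` must be uniformly spaced")
  if (!any(times < 0) || !any(times >= 0))
    stop("`times` must span stimulus onset (t = 0)")
  condition <- as.character(condition)
  if (length(condition) != nrow(data))
    stop("`condition` must have one label per trial")
  modality <- rep_len(as.character(modality), nrow(data))
  structure(
    list(subject_id = as.character(subject_id), channel = as.character(channel),
         sfreq = as.numeric(sfreq), times = times, data = data,
         condition = condition, modality = modality),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> subject", x$subject_id, "channel", x$channel, "\n")
  cat(sprintf("  %d trials x %d samples, %g Hz, %g..%g ms\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              min(x$times), max(x$times)))
  cat("  conditions:", paste(sprintf("%s(%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param e an \code{epoch_set}.
#' @return Integer trial count.
#' @export
n_trials <- function(e) nrow(e$data)

#' Baseline-correct epochs
#'
#' Subtracts, per trial, the mean amplitude over a pre-stimulus interval,
#' the standard ERP baseline convention.
#'
#' @param e an \code{epoch_set}.
#' @param interval length-2 numeric, baseline interval in ms
#'   (\code{c(from, to)}, \code{from < to}); must lie within the epoch.
#' @return The baseline-corrected \code{epoch_set}.
#' @export
baseline_correct <- function(e, interval = c(min(e$times), 0)) {
  stopifnot(inherits(e, "epoch_set"), length(interval) == 2L)
  if (interval[1] >= interval[2])
    stop("baseline `interval` must satisfy from < to")
  sel <- e$times >= interval[1] & e$times <= interval[2]
  if (!any(sel))
    stop("baseline `interval` lies outside the epoch time axis")
  e$data <- e$data - rowMeans(e$data[, sel, drop = FALSE])
  e
}

#' Induced (evoked-removed) single-trial responses
#'
#' Subtracts the condition's trial-averaged waveform from every single trial
#' of that condition, leaving only phase-inconsistent (induced) activity:
#' the trial average of the result is the zero vector by construction.
#'
#' @param e an \code{epoch_set} with at least two trials per condition.
#' @return An \code{epoch_set} of induced responses.
#' @export
induced_epochs <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  for (cond in unique(e$condition)) {
    idx <- which(e$condition == cond)
    if (length(idx) < 2L)
      stop("condition '", cond, "' has fewer than 2 trials; ",
           "the evoked average cannot be removed")
    evoked <- colMeans(e$data[idx, , drop = FALSE])
    e$data[idx, ] <- sweep(e$data[idx, , drop = FALSE], 2L, evoked)
  }
  e
}

#' Subset an epoch set by trial
#' @param e an \code{epoch_set}.
#' @param i trial indices (or logical mask).
#' @return The subsetted \code{epoch_set}.
#' @export
subset_trials <- function(e, i) {
  e$data <- e$data[i, , drop = FALSE]
  e$condition <- e$condition[i]
  e$modality <- e$modality[i]
  e
}
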