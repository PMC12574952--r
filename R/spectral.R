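#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 12-30 Hz. Band edges are shared
#' (half-power points) with no gap or overlap correction.
#'
#' @param name one of \code{"delta"}, \code{"theta"}, \code{"alpha"},
#'   \code{"beta"}; or NULL for the full table.
#' @return A one-row (or full) data.frame with name, lo, hi.
#' @export
band_definition <- function(name = NULL) {
  tab <- data.frame(name = c("delta", "theta", "alpha", "beta"),
                    lo = c(1, 4, 8, 12), hi = c(4, 8, 12, 30))
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (!nrow(row)) stop("unknown band '", name, "'")
  row
}

#' Band-limited association profile
#'
#' Band-pass filters every single trial into one canonical band,
#' recomputes the sliding variability and amplitude difference tracks, and
#' runs the two mutual partial-correlation analyses: variability
#' difference vs discriminability controlling amplitude, and amplitude
#' difference vs discriminability controlling variability.
#'
#' @param cohort list of \code{epoch_set}s.
#' @param scores per-subject discriminability scores.
#' @param band a [band_definition()] row, band name, or \code{c(lo, hi)}.
#' @param window_ms sliding-window length.
#' @param ... further arguments to [track_association()].
#' @return list with \code{band}, \code{sd_given_amp} and
#'   \code{amp_given_sd} (both \code{association_track}s), and the
#'   filtered difference tracks \code{dvar}, \code{damp}.
#' @export
band_profile <- function(cohort, scores, band, window_ms = 100, ...) {
  if (is.character(band)) band <- band_definition(band)
  if (is.data.frame(band)) band <- c(band$lo, band$hi)
  filt <- lapply(cohort, bandpass, lo = band[1], hi = band[2])
  dvar <- cohort_diff_tracks(filt, "tempSD", window_ms = window_ms)
  damp <- cohort_diff_tracks(filt, "amplitude", window_ms = window_ms)
  list(band = band,
       sd_given_amp = track_association(dvar, scores,
                                        covariate_tracks = damp, ...),
       amp_given_sd = track_association(damp, scores,
                                        covariate_tracks = dvar, ...),
       dvar = dvar, damp = damp)
}

#' Component latencies of a band-limited average waveform
#'
#' For the slow bands (delta, theta) the trial-averaged band-limited
#' waveform retains distinct N2-like and P2-like deflections: the
#' latencies of its post-stimulus minimum and of the maximum after it are
#' returned. For alpha and beta the evoked deflections are not
#' band-distinct and the extrema are taken within the 100-500 ms window.
#'
#' @param waveform list with \code{times} and \code{values} (the
#'   trial-averaged band-limited waveform), e.g. a single-row track.
#' @param band band name.
#' @return Named numeric vector \code{c(neg_peak_ms, pos_peak_ms)}.
#' @export
band_amplitude_latencies <- function(waveform, band) {
  v <- if (is.matrix(waveform$values)) waveform$values[1L, ] else waveform$values
  t <- waveform$times
  if (!length(v)) stop("empty waveform")
  if (max(v) - min(v) < 1e-12) stop("flat waveform: no component latencies")
  win <- if (band %in% c("delta", "theta")) t >= 0 else t >= 100 & t <= 500
  tv <- t[win]; vv <- v[win]
  ineg <- which.min(vv)
  after <- seq(ineg, length(vv))
  ipos <- after[which.max(vv[after])]
  c(neg_peak_ms = tv[ineg], pos_peak_ms = tv[ipos])
}
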