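#' Rating-difference discriminability
#'
#' Primary intensity-discriminability score: the mean rating of
#' high-intensity trials minus the mean rating of low-intensity trials.
#' A constant rating bias added to every trial cancels.
#'
#' @param r_high,r_low numeric rating vectors (0-10 NRS), nonempty.
#' @return Scalar in \code{[-10, 10]}.
#' @examples
#' delta_rating(c(5, 5), c(3, 3))  # 2
#' @export
delta_rating <- function(r_high, r_low) {
  if (!length(r_high) || !length(r_low))
    stop("rating vectors must be nonempty")
  mean(r_high) - mean(r_low)
}

#' AUC discriminability (probability of superiority)
#'
#' Signal-detection-theory discriminability as the area under the ROC
#' curve, estimated nonparametrically: over all (high, low) trial pairs,
#' the fraction with high > low, counting ties one half (the Mann-Whitney
#' convention). Invariant to any strictly monotone rescaling of the
#' ratings, so it is free of internal scaling bias.
#'
#' @inheritParams delta_rating
#' @return Scalar in \code{[0, 1]}.
#' @export
auc <- function(r_high, r_low) {
  if (!length(r_high) || !length(r_low))
    stop("rating vectors must be nonempty")
  cmp <- outer(r_high, r_low, function(h, l) (h > l) + 0.5 * (h == l))
  mean(cmp)
}

#' d-prime discriminability
#'
#' Mean rating difference normalised by the root mean of the two
#' per-condition variances:
#' \code{(mean(high) - mean(low)) / sqrt(0.5 * (var(high) + var(low)))},
#' with the usual \code{n - 1} variance divisor.
#'
#' @inheritParams delta_rating
#' @return Scalar.
#' @export
dprime <- function(r_high, r_low) {
  if (length(r_high) < 2L || length(r_low) < 2L)
    stop("dprime needs at least 2 trials per condition")
  pooled <- 0.5 * (stats::var(r_high) + stats::var(r_low))
  if (pooled <= 0) stop("zero pooled variance: d-prime undefined")
  (mean(r_high) - mean(r_low)) / sqrt(pooled)
}

#' Per-subject discriminability scores from a ratings table
#'
#' @param ratings ratings data.frame (see [validate_ratings()]).
#' @param metric \code{"delta_rating"}, \code{"auc"} or \code{"dprime"}.
#' @param modality modality to score (default first in the table).
#' @param high,low condition labels.
#' @return data.frame (subject_id, modality, metric, value), one row per
#'   subject, ordered by subject id.
#' @export
discrim_scores <- function(ratings, metric = c("delta_rating", "auc", "dprime"),
                           modality = NULL, high = "high", low = "low") {
  metric <- match.arg(metric)
  ratings <- validate_ratings(ratings)
  if (is.null(modality)) modality <- ratings$modality[1L]
  r <- ratings[ratings$modality == modality, ]
  if (!nrow(r)) stop("no ratings for modality '", modality, "'")
  fn <- switch(metric, delta_rating = delta_rating, auc = auc, dprime = dprime)
  ids <- sort(unique(r$subject_id))
  vals <- vapply(ids, function(id) {
    fn(r$rating[r$subject_id == id & r$condition == high],
       r$rating[r$subject_id == id & r$condition == low])
  }, 0)
  data.frame(subject_id = ids, modality = modality, metric = metric,
             value = unname(vals))
}

#' High/low pairs of an ordered intensity ladder
#'
#' Multi-level designs analyse every (higher, lower) pair of stimulus
#' intensities; \code{k} levels give \code{choose(k, 2)} pairs (6 pairs for
#' 4 levels, 15 for 6).
#'
#' @param levels ordered vector of intensity labels (low to high).
#' @return data.frame with columns \code{high}, \code{low}.
#' @export
intensity_pairs <- function(levels) {
  k <- length(levels)
  if (k < 2L) stop("need at least two intensity levels")
  idx <- utils::combn(k, 2L)
  data.frame(high = levels[idx[2L, ]], low = levels[idx[1L, ]],
             stringsAsFactors = FALSE)
}
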