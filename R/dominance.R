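r2_two <- function(r1, r2, r12) {
  # centred R^2 of y ~ x1 + x2 from pairwise correlations
  (r1^2 + r2^2 - 2 * r1 * r2 * r12) / (1 - r12^2)
}

#' Total dominance of two predictors
#'
#' Dominance analysis decomposes the determination coefficient of the full
#' two-predictor regression into per-predictor "total dominance" shares:
#' \code{td1 = (R2_full - R2_2 + R2_1) / 2} and symmetrically for
#' \code{td2}, where \code{R2_j} is the R-squared of the one-predictor
#' model. The shares sum to \code{R2_full} exactly. With orthogonal
#' predictors \code{td_j} collapses to \code{R2_j}; with suppressor
#' structure a share can be negative (it is reported, not clamped).
#'
#' @param y response (discriminability scores).
#' @param x1,x2 predictors (variability and amplitude differences).
#' @return list with \code{r2_full}, \code{td1}, \code{td2}.
#' @export
total_dominance <- function(y, x1, x2) {
  n <- length(y)
  if (n < 5L || length(x1) != n || length(x2) != n)
    stop("need aligned vectors of length >= 5")
  if (!all(is.finite(c(y, x1, x2)))) stop("inputs must be finite")
  r12 <- stats::cor(x1, x2)
  if (abs(r12) > 1 - 1e-10)
    stop("predictors are collinear: dominance undefined")
  r1 <- stats::cor(x1, y); r2 <- stats::cor(x2, y)
  r2_full <- r2_two(r1, r2, r12)
  td1 <- (r2_full - r2^2 + r1^2) / 2
  td2 <- (r2_full - r1^2 + r2^2) / 2
  list(r2_full = r2_full, td1 = td1, td2 = td2)
}

#' Point-by-point dominance decomposition
#'
#' Runs [total_dominance()] at every window center with the variability
#' difference and amplitude difference as competing predictors of the
#' discriminability score.
#'
#' @param scores per-subject scores (vector or [discrim_scores()] frame).
#' @param var_tracks,amp_tracks track lists (times + subjects x windows
#'   delta matrices), as from [cohort_diff_tracks()].
#' @return A \code{dominance_track}: list with \code{times},
#'   \code{r2_full}, \code{td_var}, \code{td_amp}.
#' @export
dominance_track <- function(scores, var_tracks, amp_tracks) {
  X <- var_tracks$delta; Z <- amp_tracks$delta
  if (!all(dim(X) == dim(Z)))
    stop("variability and amplitude tracks must have the same shape")
  if (is.data.frame(scores)) {
    m <- match(rownames(X), scores$subject_id)
    if (anyNA(m)) stop("subjects in tracks and scores do not match")
    scores <- scores$value[m]
  }
  r1 <- col_corr(X, scores)
  r2 <- col_corr(Z, scores)
  r12 <- col_corr(X, Z)
  r2f <- r2_two(r1, r2, r12)
  structure(list(times = var_tracks$times, r2_full = r2f,
                 td_var = (r2f - r2^2 + r1^2) / 2,
                 td_amp = (r2f - r1^2 + r2^2) / 2),
            class = "dominance_track")
}

#' @export
as.data.frame.dominance_track <- function(x, ...) {
  data.frame(time_ms = x$times, r2_full = x$r2_full, td_var = x$td_var,
             td_amp = x$td_amp)
}
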