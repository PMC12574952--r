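col_center <- function(X) sweep(X, 2L, colMeans(X))

# correlation of each column of X with y (or with the matching column of Y)
col_corr <- function(X, y) {
  Xc <- col_center(X)
  if (is.matrix(y)) {
    Yc <- col_center(y)
    colSums(Xc * Yc) / sqrt(colSums(Xc^2) * colSums(Yc^2))
  } else {
    yc <- y - mean(y)
    as.vector(crossprod(Xc, yc)) / sqrt(colSums(Xc^2) * sum(yc^2))
  }
}

#' Point-by-point association between difference tracks and discriminability
#'
#' Correlates, across subjects, the high-minus-low metric value at every
#' window center with the per-subject discriminability score; optionally a
#' partial correlation controlling for a covariate track (typically the
#' amplitude difference) at the same time point. Two-tailed p values;
#' Benjamini-Hochberg FDR flags computed over post-stimulus window centers
#' only (the correction family is one track at one channel); JZS Bayes
#' factors per point.
#'
#' @param tracks list with \code{times} and \code{delta} (subjects x
#'   windows matrix), as returned by [cohort_diff_tracks()].
#' @param scores numeric per-subject scores aligned with the rows of
#'   \code{delta} (or a [discrim_scores()] data.frame; rows are matched by
#'   \code{subject_id}).
#' @param covariate_tracks optional covariate track list of the same shape;
#'   when given, partial correlations are computed.
#' @param method \code{"pearson"} (default) or \code{"spearman"} (ranks
#'   taken before any partialling).
#' @param alpha FDR level.
#' @param compute_bf compute per-point JZS Bayes factors (set FALSE to
#'   skip, e.g. inside resampling loops).
#' @param rscale JZS prior scale.
#' @return An \code{association_track}: list with \code{times}, \code{r},
#'   \code{p}, \code{q_sig}, \code{bf}, \code{kind}, \code{covariate_name},
#'   \code{n}, \code{alpha}.
#' @export
track_association <- function(tracks, scores, covariate_tracks = NULL,
                              method = c("pearson", "spearman"),
                              alpha = 0.05, compute_bf = TRUE,
                              rscale = sqrt(2) / 2) {
  method <- match.arg(method)
  X <- tracks$delta
  times <- tracks$times
  if (is.data.frame(scores)) {
    if (is.null(rownames(X)))
      stop("delta matrix needs subject-id rownames to align with scores")
    m <- match(rownames(X), scores$subject_id)
    if (anyNA(m)) stop("subjects in tracks and scores do not match")
    scores <- scores$value[m]
  }
  if (length(scores) != nrow(X))
    stop("scores must align with the rows of the delta matrix")
  Z <- NULL
  if (!is.null(covariate_tracks)) {
    Z <- covariate_tracks$delta
    if (!all(dim(Z) == dim(X)))
      stop("covariate tracks must match the delta matrix in shape")
  }
  if (method == "spearman") {
    X <- apply(X, 2L, rank)
    scores <- rank(scores)
    if (!is.null(Z)) Z <- apply(Z, 2L, rank)
  }
  n <- nrow(X)
  if (is.null(Z)) {
    r <- col_corr(X, scores)
    df <- n - 2
    kind <- method
    covname <- NULL
  } else {
    rxy <- col_corr(X, scores)
    rxz <- col_corr(X, Z)
    ryz <- col_corr(Z, scores)
    den <- sqrt(pmax((1 - rxz^2) * (1 - ryz^2), .Machine$double.eps))
    r <- (rxy - rxz * ryz) / den
    df <- n - 3
    kind <- "partial"
    covname <- "covariate"
  }
  p <- corr_p(r, df)
  post <- times >= 0
  q_sig <- rep(FALSE, length(times))
  q_sig[post] <- fdr_bh(p[post], alpha)
  bf <- rep(NA_real_, length(times))
  if (compute_bf)
    bf <- vapply(r, function(ri)
      bf_jzs_corr(r = ri, n = if (is.null(Z)) n else n - 1, rscale = rscale), 0)
  structure(list(times = times, r = r, p = p, q_sig = q_sig, bf = bf,
                 kind = kind, covariate_name = covname, n = n,
                 alpha = alpha),
            class = "association_track")
}

#' @export
print.association_track <- function(x, ...) {
  cat(sprintf("<association_track> %s, n = %d, %d points, %d FDR-significant (alpha = %g)\n",
              x$kind, x$n, length(x$times), sum(x$q_sig), x$alpha))
  invisible(x)
}

#' @export
as.data.frame.association_track <- function(x, ...) {
  data.frame(time_ms = x$times, r = x$r, p = x$p, fdr_sig = x$q_sig,
             bf = x$bf)
}

#' Align ratings with the trials of an epoch set
#'
#' Matches each trial of \code{e} to its rating by (subject, modality,
#' condition, within-condition occurrence).
#'
#' @param e an \code{epoch_set}.
#' @param ratings ratings data.frame.
#' @return Numeric vector of per-trial ratings in trial order.
#' @export
ratings_for_epochs <- function(e, ratings) {
  occ <- stats::ave(seq_along(e$condition), e$condition, FUN = seq_along)
  key_e <- paste(e$subject_id, e$modality, e$condition, occ)
  key_r <- paste(ratings$subject_id, ratings$modality, ratings$condition,
                 ratings$trial_index)
  m <- match(key_e, key_r)
  if (anyNA(m))
    stop("no rating found for ", sum(is.na(m)), " trial(s) of subject ",
         e$subject_id)
  ratings$rating[m]
}

#' Intra-individual (single-trial) association
#'
#' For each subject, correlates the single-trial metric value at every
#' window center with the single-trial rating (across trials of all
#' conditions), Fisher-z transforms the coefficients, and tests the group
#' of z values against zero with a one-sample t test per time point; FDR
#' over post-stimulus points. Subjects with zero rating variance are
#' excluded (with a warning).
#'
#' @param cohort list of \code{epoch_set}s.
#' @param ratings ratings data.frame.
#' @param metric,window_ms,step_ms passed to [sliding_track()].
#' @param alpha FDR level.
#' @return list with \code{times}, \code{mean_z}, \code{t}, \code{p},
#'   \code{q_sig}, \code{n_subjects}, \code{excluded}.
#' @export
intra_individual <- function(cohort, ratings, metric = "tempSD",
                             window_ms = 100, step_ms = 1, alpha = 0.05) {
  zrows <- list()
  excluded <- character()
  for (e in cohort) {
    rat <- ratings_for_epochs(e, ratings)
    if (length(rat) < 5L)
      stop("intra-individual analysis needs >= 5 trials per subject")
    if (stats::sd(rat) == 0) {
      excluded <- c(excluded, e$subject_id)
      next
    }
    tr <- sliding_track(e, metric, window_ms = window_ms, step_ms = step_ms)
    r <- col_corr(tr$values, rat)
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    zrows[[e$subject_id]] <- atanh(r)
    times <- tr$times
  }
  if (length(excluded))
    warning("excluded for zero rating variance: ",
            paste(excluded, collapse = ", "))
  if (length(zrows) < 3L)
    stop("too few subjects with rating variance for a group test")
  Z <- do.call(rbind, zrows)
  ns <- nrow(Z)
  mz <- colMeans(Z)
  sz <- apply(Z, 2L, stats::sd)
  t <- mz / (sz / sqrt(ns))
  p <- 2 * stats::pt(abs(t), ns - 1, lower.tail = FALSE)
  post <- times >= 0
  q_sig <- rep(FALSE, length(times))
  q_sig[post] <- fdr_bh(p[post], alpha)
  list(times = times, mean_z = mz, t = t, p = p, q_sig = q_sig,
       n_subjects = ns, excluded = excluded)
}

#' Inter-individual sensitivity analysis
#'
#' Tests whether condition-pooled variability tracks mean sensory
#' sensitivity rather than discriminability: per subject, the metric track
#' averaged over all trials regardless of intensity is partially
#' correlated, point by point, with the subject's mean rating
#' ((high + low) / 2), controlling for the pooled mean-amplitude track.
#'
#' @param cohort list of \code{epoch_set}s.
#' @param ratings ratings data.frame.
#' @param metric,window_ms,step_ms passed to [sliding_track()].
#' @param ... further arguments to [track_association()].
#' @return An \code{association_track}.
#' @export
sensitivity_analysis <- function(cohort, ratings, metric = "tempSD",
                                 window_ms = 100, step_ms = 1, ...) {
  if (length(cohort) < 4L)
    stop("sensitivity analysis needs at least 4 subjects")
  pooled <- function(e, met) {
    tr <- sliding_track(e, met, window_ms = window_ms, step_ms = step_ms)
    list(times = tr$times, v = colMeans(tr$values))
  }
  sd_rows <- lapply(cohort, pooled, met = metric)
  amp_rows <- lapply(cohort, pooled, met = "amplitude")
  ids <- vapply(cohort, function(e) e$subject_id, "")
  sd_mat <- do.call(rbind, lapply(sd_rows, `[[`, "v"))
  amp_mat <- do.call(rbind, lapply(amp_rows, `[[`, "v"))
  rownames(sd_mat) <- rownames(amp_mat) <- ids
  mean_rating <- vapply(ids, function(id)
    mean(ratings$rating[ratings$subject_id == id]), 0)
  track_association(list(times = sd_rows[[1L]]$times, delta = sd_mat),
                    mean_rating,
                    covariate_tracks = list(times = sd_rows[[1L]]$times,
                                            delta = amp_mat), ...)
}

#' ROI-level (partial) correlation with discriminability
#'
#' Convenience wrapper for the scatterplot-level analysis: finds the peak
#' region of interest of the subject-averaged difference track, averages
#' each subject's track over it, and correlates (partially, when a
#' covariate is given) with the scores.
#'
#' @param tracks,covariate_tracks,scores as in [track_association()].
#' @param halfwidth_ms ROI half-width in ms.
#' @param mode extremum type for the ROI search (\code{"max"} for SD,
#'   \code{"min"} for PE troughs).
#' @param compute_bf attach a JZS Bayes factor.
#' @return list with \code{roi} (ms interval), \code{r}, \code{p},
#'   \code{bf}, \code{n}.
#' @export
roi_association <- function(tracks, scores, covariate_tracks = NULL,
                            halfwidth_ms = 10, mode = "max",
                            compute_bf = TRUE) {
  if (is.data.frame(scores)) {
    m <- match(rownames(tracks$delta), scores$subject_id)
    if (anyNA(m)) stop("subjects in tracks and scores do not match")
    scores <- scores$value[m]
  }
  roi <- peak_roi(list(times = tracks$times, values = colMeans(tracks$delta)),
                  halfwidth_ms = halfwidth_ms, mode = mode)
  x <- roi_value(list(times = tracks$times, values = tracks$delta), roi)
  n <- length(x)
  if (is.null(covariate_tracks)) {
    ct <- pearson_corr(x, scores)
    bf_n <- n
  } else {
    z <- roi_value(list(times = covariate_tracks$times,
                        values = covariate_tracks$delta), roi)
    ct <- partial_corr(x, scores, z)
    bf_n <- n - 1
  }
  bf <- if (compute_bf) bf_jzs_corr(r = ct$r, n = bf_n) else NA_real_
  list(roi = roi, r = ct$r, p = ct$p, bf = bf, n = n)
}
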