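#' Greedy cross-modality rating matching
#'
#' Pairs each pain subject with an other-modality subject whose
#' condition-mean ratings are close: a candidate must differ by at most
#' \code{tol} in both the high- and low-condition means (the worked rule:
#' means of 6 and 4 admit candidates rated 5.5-6.5 and 3.5-4.5). Among the
#' candidates still unpaired, those with the smallest total absolute error
#' (|dhigh| + |dlow|) are kept; a single minimiser is taken
#' deterministically, ties are broken uniformly at random (seeded). Pain
#' subjects are visited in ascending subject-id order (greedy matching is
#' order-dependent; the order is fixed so results are reproducible). A
#' subject with no candidate stays unmatched.
#'
#' @param pain_means,other_means data.frames (subject_id, high, low) of
#'   per-subject condition-mean ratings (see [rating_means()]).
#' @param tol per-condition tolerance (default 0.5 NRS units).
#' @param seed integer seed for tie-breaking.
#' @return A \code{match_result}: list with \code{pairs} (data.frame
#'   pain_id, other_id, err_high, err_low) and \code{unmatched} (pain
#'   subject ids).
#' @export
match_ratings <- function(pain_means, other_means, tol = 0.5, seed = 1) {
  if (!nrow(pain_means) || !nrow(other_means)) stop("empty rating tables")
  if (tol <= 0) stop("tol must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pain_means <- pain_means[order(pain_means$subject_id), ]
  taken <- rep(FALSE, nrow(other_means))
  pairs <- list()
  unmatched <- character()
  for (i in seq_len(nrow(pain_means))) {
    eh <- abs(other_means$high - pain_means$high[i])
    el <- abs(other_means$low - pain_means$low[i])
    cand <- which(!taken & eh <= tol & el <= tol)
    if (!length(cand)) {
      unmatched <- c(unmatched, pain_means$subject_id[i])
      next
    }
    tot <- eh[cand] + el[cand]
    best <- cand[tot <= min(tot) + 1e-12]
    pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    taken[pick] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      pain_id = pain_means$subject_id[i],
      other_id = other_means$subject_id[pick],
      err_high = eh[pick], err_low = el[pick])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(pain_id = character(), other_id = character(),
                  err_high = numeric(), err_low = numeric())
  structure(list(pairs = pairs, unmatched = unmatched, tol = tol),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), %d unmatched (tol %.2f)\n",
              nrow(x$pairs), length(x$unmatched), x$tol))
  invisible(x)
}

#' Compare ROI associations between matched subsets
#'
#' Runs the peak-ROI partial-correlation analysis separately on the
#' matched pain subjects and the matched other-modality subjects, then
#' compares the two coefficients. The subsets contain different
#' individuals, so the independent-groups Fisher z test is used (for two
#' correlations sharing a variable on the same cases use [steiger_z()]).
#'
#' @param match a [match_ratings()] result with at least \code{min_pairs}
#'   pairs.
#' @param pain_data,other_data lists with \code{tracks} (delta track list,
#'   rownames = subject ids), \code{scores}, and optionally \code{cov}
#'   (covariate track list) for each modality.
#' @param min_pairs minimum number of pairs (default 10).
#' @return list with \code{pain} and \code{other} ROI results (see
#'   [roi_association()]) and \code{diff} (z, p).
#' @export
matched_contrast <- function(match, pain_data, other_data, min_pairs = 10) {
  if (!nrow(match$pairs)) stop("empty match: nothing to contrast")
  if (nrow(match$pairs) < min_pairs)
    stop("too few matched pairs (", nrow(match$pairs), " < ", min_pairs, ")")
  subset_data <- function(dat, ids) {
    keep <- rownames(dat$tracks$delta) %in% ids
    if (sum(keep) < 4L) stop("matched subset too small")
    out <- list(tracks = list(times = dat$tracks$times,
                              delta = dat$tracks$delta[keep, , drop = FALSE]),
                scores = if (is.data.frame(dat$scores))
                  dat$scores[dat$scores$subject_id %in% ids, ]
                else dat$scores[keep])
    if (!is.null(dat$cov))
      out$cov <- list(times = dat$cov$times,
                      delta = dat$cov$delta[keep, , drop = FALSE])
    out
  }
  dp <- subset_data(pain_data, match$pairs$pain_id)
  do <- subset_data(other_data, match$pairs$other_id)
  res_p <- roi_association(dp$tracks, dp$scores, covariate_tracks = dp$cov)
  res_o <- roi_association(do$tracks, do$scores, covariate_tracks = do$cov)
  cmp <- fisher_z_independent(res_p$r, res_o$r, res_p$n, res_o$n)
  list(pain = res_p, other = res_o, diff = cmp)
}
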