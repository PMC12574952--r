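corr_p <- function(r, df) {
  # two-tailed p for a (partial) correlation via the t transform
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df, lower.tail = FALSE)
}

#' Pearson and Spearman correlation with two-tailed p
#'
#' Product-moment (or rank) correlation with the usual t-distributed
#' two-tailed p value on \code{n - 2} degrees of freedom. Spearman is the
#' Pearson correlation of ranks, the variant used for small multi-level
#' designs.
#'
#' @param x,y numeric vectors, finite, length >= 3.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need aligned vectors of length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, p = corr_p(r, n - 2), n = n)
}

#' @rdname pearson_corr
#' @export
spearman_corr <- function(x, y) {
  out <- pearson_corr(rank(x), rank(y))
  out
}

#' Partial correlation controlling for one covariate
#'
#' Correlation of the residuals of \code{x ~ z} and \code{y ~ z};
#' two-tailed p from a t statistic on \code{n - 3} degrees of freedom.
#'
#' @param x,y,z aligned numeric vectors, length >= 4.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
partial_corr <- function(x, y, z) {
  n <- length(x)
  if (n < 4L || length(y) != n || length(z) != n)
    stop("need aligned vectors of length >= 4")
  if (stats::sd(z) == 0) stop("covariate has zero variance")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  num <- rxy - rxz * ryz
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den < 1e-12) {
    # z collinear with x or y: residual variance vanishes; the 0/0 limit is 0
    if (abs(num) < 1e-10) return(list(r = 0, p = 1, n = n))
    stop("covariate collinear with x or y: partial correlation undefined")
  }
  r <- num / den
  list(r = r, p = corr_p(r, n - 3), n = n)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up false-discovery-rate procedure: flags the hypotheses kept at
#' level \code{alpha}.
#'
#' @param p numeric vector of p values in \code{[0, 1]}.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector, TRUE where significant after correction.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= alpha
}

jzs_log_integrand <- function(logg, n, r2, p, rscale) {
  # Zellner-Siow mixture: g ~ InvGamma(1/2, n * rscale^2 / 2); the extra
  # log(g) term is the Jacobian of integrating over log g; log1p terms use
  # their large-g asymptote to stay finite at extreme abscissae
  a <- n * rscale^2 / 2
  l1p <- function(lg, scale = 1) {
    u <- lg + log(scale)
    ifelse(u > 30, u, log1p(exp(pmax(u, -745))))
  }
  0.5 * log(a) - lgamma(0.5) - 1.5 * logg - a * exp(-logg) +
    ((n - 1 - p) / 2) * l1p(logg) -
    ((n - 1) / 2) * l1p(logg, 1 - r2) + logg
}

#' JZS Bayes factor for a correlation
#'
#' Bayes factor (alternative over null) for a linear association under the
#' Jeffreys-Zellner-Siow prior: a Cauchy prior of scale \code{rscale} on
#' the standardised slope, implemented as the Zellner-Siow inverse-gamma
#' mixture over Zellner's g and integrated by adaptive quadrature over
#' \code{log g}. Values above 1 favour the association; Kass-Raftery bins
#' are available via [bf_category()].
#'
#' @param x,y aligned numeric vectors (length >= 5), or pass \code{r =}
#'   and \code{n =} directly.
#' @param r,n observed correlation and sample size (alternative interface;
#'   for a partial correlation pass the residual degrees of freedom
#'   \code{n - n_covariates} as \code{n}).
#' @param rscale Cauchy prior scale (default \code{sqrt(2) / 2}).
#' @return Positive scalar Bayes factor.
#' @export
bf_jzs_corr <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                        rscale = sqrt(2) / 2) {
  if (is.null(r)) {
    if (length(x) < 5L || length(y) != length(x))
      stop("need aligned vectors of length >= 5")
    r <- stats::cor(x, y)
    n <- length(x)
  }
  if (n < 5L) stop("need n >= 5")
  r2 <- min(r^2, 1 - 1e-12)
  f <- function(lg) exp(jzs_log_integrand(lg, n, r2, p = 1, rscale = rscale))
  q <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-9, abs.tol = 0,
                        stop.on.error = FALSE)
  if (q$message != "OK" || !is.finite(q$value) || q$value <= 0)
    stop("JZS quadrature failed (", q$message, "); r=", signif(r, 4),
         " n=", n)
  q$value
}

#' Kass-Raftery category of a Bayes factor
#'
#' Bins: below 1 the BF favours the null and the reciprocal is reported;
#' 1-3.3 barely worth mentioning; 3.3-10 substantial; 10-100 strong;
#' above 100 decisive. Boundary values go to the upper bin.
#'
#' @param bf positive scalar Bayes factor.
#' @return list with \code{label}, \code{favours} ("alternative" or
#'   "null"), and \code{reported} (the BF, or its reciprocal when the null
#'   is favoured).
#' @export
bf_category <- function(bf) {
  if (!is.finite(bf) || bf <= 0) stop("Bayes factor must be positive")
  if (bf < 1)
    return(list(label = "evidence for the null (reciprocal reported)",
                favours = "null", reported = 1 / bf))
  label <- if (bf < 3.3) "barely worth mentioning"
  else if (bf < 10) "substantial"
  else if (bf < 100) "strong"
  else "decisive"
  list(label = label, favours = "alternative", reported = bf)
}

#' Steiger's z test for two dependent correlations
#'
#' Tests the difference between two correlations that share one variable
#' (\code{r_jk} vs \code{r_jh}, measured on the same \code{n} cases), using
#' Fisher z transforms and the dependent-correlation covariance term with
#' the pooled correlation.
#'
#' @param r_jk,r_jh the two correlations sharing variable j.
#' @param r_kh correlation between the two non-shared variables.
#' @param n sample size (>= 10).
#' @return list with \code{z} and two-tailed \code{p}.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  if (n < 10L) stop("Steiger's z needs n >= 10")
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fisher z test for two independent correlations
#'
#' For correlations estimated on non-overlapping groups (e.g. disjoint
#' matched subsets), the independent-groups z test on Fisher transforms.
#'
#' @param r1,r2 the two correlations.
#' @param n1,n2 the group sizes (>= 4).
#' @return list with \code{z} and two-tailed \code{p}.
#' @export
fisher_z_independent <- function(r1, r2, n1, n2) {
  if (n1 < 4L || n2 < 4L) stop("need n >= 4 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
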