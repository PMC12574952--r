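test_that("pearson and spearman correlations behave on closed-form cases", {
  x <- c(1, 2, 4)
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, c(2, 4, 8))$r, 1)
  # 3-point textbook closed form
  y <- c(2, 1, 5)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_corr(x, y)$r, r_ref, tolerance = 1e-12)
  set.seed(4)
  a <- rnorm(1000)
  expect_lt(abs(pearson_corr(a, sample(a))$r), 0.1)
  b <- rnorm(20)
  expect_equal(spearman_corr(exp(3 * a[1:20]), b)$r, spearman_corr(a[1:20], b)$r)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(50); z <- rnorm(50)
    y <- 0.4 * x + 0.5 * z + rnorm(50)
    ref <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    got <- partial_corr(x, y, z)
    expect_equal(got$r, ref, tolerance = 1e-10)
    t_ref <- ref * sqrt(47 / (1 - ref^2))
    expect_equal(got$p, 2 * pt(abs(t_ref), 47, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # orthogonal covariate leaves the simple correlation untouched
  x <- rnorm(64); y <- rnorm(64)
  z <- resid(lm(rnorm(64) ~ x + y))      # orthogonal by construction
  expect_equal(partial_corr(x, y, z)$r, cor(x, y), tolerance = 1e-12)
  # controlling y for itself kills the association
  expect_equal(partial_corr(x, y, y)$r, 0, tolerance = 1e-12)
  expect_error(partial_corr(x, y, rep(2, 64)), "zero variance")
})

test_that("BH-FDR flags equal the brute-force step-up definition", {
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)))
  expect_false(any(fdr_bh(rep(1, 10))))
  expect_true(fdr_bh(0.04))
  set.seed(77)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)
    a <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, a), bh_brute(p, a))
  }
})

test_that("JZS Bayes factor matches a fine-grid quadrature oracle", {
  oracle <- function(r, n, rscale = sqrt(2) / 2) {
    a <- n * rscale^2 / 2
    lg <- seq(-30, 60, length.out = 40001)
    g <- exp(lg)
    logf <- 0.5 * log(a) - lgamma(0.5) - 1.5 * lg - a / g +
      ((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p(g * (1 - r^2)) + lg
    mx <- max(logf)
    exp(mx) * sum(exp(logf - mx)) * (lg[2] - lg[1])
  }
  for (r in c(0, 0.3, 0.6, 0.85)) for (n in c(10, 40, 120)) {
    expect_equal(bf_jzs_corr(r = r, n = n), oracle(r, n), tolerance = 0.01)
  }
})

test_that("JZS Bayes factor favours the null at r = 0 and grows with |r|", {
  set.seed(12)
  x <- rnorm(50); y <- rnorm(50)
  y <- resid(lm(y ~ x))                 # force r = 0 exactly
  expect_lt(bf_jzs_corr(x, y), 1)
  bfs <- vapply(seq(0, 0.9, by = 0.1), function(r)
    bf_jzs_corr(r = r, n = 60), 0)
  expect_true(all(diff(bfs) > 0))
  # symmetric in the sign of r (two-sided evidence)
  expect_equal(bf_jzs_corr(r = 0.4, n = 30), bf_jzs_corr(r = -0.4, n = 30))
})

test_that("Bayes factor categories follow the published bins", {
  lo <- bf_category(0.2)
  expect_equal(lo$favours, "null")
  expect_equal(lo$reported, 5)
  expect_equal(bf_category(56.16)$label, "strong")
  expect_equal(bf_category(2)$label, "barely worth mentioning")
  expect_equal(bf_category(3.3)$label, "substantial")   # boundary -> upper bin
  expect_equal(bf_category(10)$label, "strong")
  expect_equal(bf_category(150)$label, "decisive")
  expect_error(bf_category(-1), "positive")
})

test_that("Steiger's z is zero for equal correlations and grows with the gap", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 100)$z, 0)
  zs <- vapply(seq(0, 0.4, by = 0.1), function(d)
    abs(steiger_z(0.5, 0.5 - d, 0.3, 100)$z), 0)
  expect_true(all(diff(zs) > 0))
  expect_error(steiger_z(1, 0.5, 0.3, 100), "strictly inside")
})

test_that("Steiger's z agrees with a bootstrap test of dependent correlations", {
  # shared-variable triples; decision agreement at alpha = 0.05
  set.seed(55)
  agree <- 0; runs <- 20
  for (run in 1:20) {
    n <- 200
    j <- rnorm(n)
    beta <- sample(c(0, 0.5), 1)
    k <- 0.5 * j + rnorm(n)
    h <- beta * j + rnorm(n)
    st <- steiger_z(cor(j, k), cor(j, h), cor(k, h), n)
    boot <- replicate(500, {
      i <- sample(n, replace = TRUE)
      cor(j[i], k[i]) - cor(j[i], h[i])
    })
    ci <- quantile(boot, c(0.025, 0.975))
    boot_rej <- ci[1] > 0 || ci[2] < 0
    agree <- agree + ((st$p < 0.05) == boot_rej)
  }
  expect_gte(agree / runs, 0.9)
})

test_that("independent-groups Fisher z test is calibrated and directional", {
  out <- fisher_z_independent(0.6, 0.6, 80, 90)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
  expect_lt(fisher_z_independent(0.7, 0.1, 100, 100)$p, 0.001)
})
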