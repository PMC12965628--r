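test_that("covariate-adjusted permutation test behaves at the extremes", {
  set.seed(1)
  a <- rnorm(15); b <- rnorm(15) + 50     # effect >> noise
  res <- permutation_test_covadj(a, b, n_perm = 999, seed = 3)
  expect_equal(res$p, 1 / 1000)           # attainable minimum
  # two-sided: invariant to swapping group labels
  res2 <- permutation_test_covadj(b, a, n_perm = 999, seed = 3)
  expect_equal(res2$p, res$p)
  expect_equal(res2$statistic, -res$statistic, tolerance = 1e-12)
  expect_warning(r0 <- permutation_test_covadj(rep(1, 5), rep(1, 6),
                                               n_perm = 99, seed = 1),
                 "constant")
  expect_equal(r0$p, 1)
  expect_error(permutation_test_covadj(1:2, 1:5), ">= 3")
})

test_that("Freedman-Lane controls type-I error under the null", {
  reps <- 300
  n <- 20
  pvals <- vapply(seq_len(reps), function(r) {
    set.seed(r)
    age <- rnorm(n, 50, 8)
    y <- 0.05 * age + rnorm(n)            # outcome depends on covariate only
    permutation_test_covadj(y[1:10], y[11:20],
                            cbind(age = age[1:10]), cbind(age = age[11:20]),
                            n_perm = 199, seed = 10000 + r)$p
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  ci99 <- qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci99 + 1e-9)
})

test_that("covariate adjustment removes confounding that fools the raw test", {
  # outcome fully determined by a covariate that differs between groups:
  # the adjusted test stays near-nominal, the unadjusted one rejects wildly
  reps <- 80
  padj <- numeric(reps); praw <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(2000 + r)
    age_a <- rnorm(12, 40, 3); age_b <- rnorm(12, 60, 3)
    y_a <- 0.5 * age_a + rnorm(12, sd = 0.5)
    y_b <- 0.5 * age_b + rnorm(12, sd = 0.5)
    padj[r] <- permutation_test_covadj(y_a, y_b, cbind(age_a), cbind(age_b),
                                       n_perm = 199, seed = r)$p
    praw[r] <- permutation_test_covadj(y_a, y_b, n_perm = 199, seed = r)$p
  }
  expect_gt(mean(praw <= 0.05), 0.9)
  expect_lt(mean(padj <= 0.05), 0.2)
})

test_that("without covariates the scheme reduces to a plain permutation test", {
  # Freedman-Lane with an intercept-only reduced model permutes the centred
  # outcome: p must equal a plain label-permutation test run on the same
  # permutation stream
  set.seed(5)
  y <- rnorm(16); g <- rep(0:1, each = 8)
  res <- permutation_test_covadj(y[g == 0], y[g == 1], n_perm = 499,
                                 seed = 77)
  # independent plain implementation with the same stream
  tfun <- function(yy) {
    t.test(yy[g == 0], yy[g == 1], var.equal = TRUE)$statistic
  }
  t_obs <- tfun(y)
  f0 <- mean(y); r0 <- y - f0
  set.seed(77L)
  perms <- replicate(499, sample.int(16))
  t_star <- apply(perms, 2, function(ix) tfun(f0 + r0[ix]))
  p_plain <- (sum(abs(t_star) >= abs(t_obs)) + 1) / 500
  expect_equal(res$p, p_plain, tolerance = 1e-12)
  expect_equal(abs(res$statistic), abs(unname(t_obs)), tolerance = 1e-10)
})

test_that("paired sign-flip test behaves at the extremes and under the null", {
  pre <- c(5, 6, 7, 8, 9)
  expect_warning(r <- paired_permutation_test(pre, pre, n_perm = 99),
                 "zero")
  expect_equal(r$p, 1)
  # overwhelming effect at n = 20 pairs: only the two all-same-sign flips
  # (probability 2^-19 each) tie the observed statistic -> minimum p
  set.seed(30)
  pre20 <- rnorm(20)
  res <- paired_permutation_test(pre20, pre20 + 10 + rnorm(20, sd = 0.1),
                                 n_perm = 999, seed = 2)
  expect_equal(res$p, 1 / 1000)
  # type-I calibration under exchangeable zero-mean differences
  reps <- 300
  pvals <- vapply(seq_len(reps), function(r) {
    set.seed(r)
    d <- rnorm(12)
    paired_permutation_test(rep(0, 12), d, n_perm = 199,
                            seed = 5000 + r)$p
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  ci99 <- qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci99 + 1e-9)
})

test_that("BH correction matches the hand-computed step-up", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(unname(r$q), rep(0.04, 4))
  expect_equal(fdr_bh(0.37)$q, 0.37)              # single p: q = p
  expect_false(any(fdr_bh(rep(1, 10))$rejected))  # all p = 1: no rejections
  expect_equal(fdr_bh(numeric(0))$q, numeric(0))
  r2 <- fdr_bh(c(0.001, 0.5, 0.9))
  expect_true(all(r2$q >= c(0.001, 0.5, 0.9)))    # q >= p within a family
  expect_error(fdr_bh(c(0.5, 2)), "0, 1")
})

test_that("VAS percent change uses the relief-positive orientation", {
  expect_equal(vas_percent_change(6.25, 2.26), 100 * (6.25 - 2.26) / 6.25)
  expect_equal(vas_percent_change(6.25, 2.26), 63.84)
  expect_equal(vas_percent_change(5, 5), 0)
  expect_equal(vas_percent_change(7, 0), 100)
  expect_error(vas_percent_change(0, 1), "vas_pre")
})

test_that("partial correlation equals Pearson on covariate-free data and
           matches an independent residual oracle", {
  set.seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- partial_correlation(x, y)
  expect_equal(res$r, cor(x, y), tolerance = 1e-12)
  expect_equal(res$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(partial_correlation(x, x)$r, 1, tolerance = 1e-12)

  covs <- cbind(age = rnorm(30, 50, 5), sex = rbinom(30, 1, 0.5))
  y2 <- 0.3 * covs[, "age"] + rnorm(30)
  res2 <- partial_correlation(x, y2, covs)
  # oracle: residuals from R's lm(), then plain Pearson
  rx <- residuals(lm(x ~ covs))
  ry <- residuals(lm(y2 ~ covs))
  expect_equal(res2$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(res2$df, 30 - 2 - 2)
  expect_error(partial_correlation(1:4, 1:4, cbind(rnorm(4), rnorm(4))),
               "n > 2")
})

test_that("partial correlation of covariate-driven variables is null", {
  reps <- 200
  rs <- vapply(seq_len(reps), function(r) {
    set.seed(300 + r)
    z <- rnorm(40)
    x <- 2 * z + rnorm(40)
    y <- -z + rnorm(40)
    partial_correlation(x, y, cbind(z))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(reps) + 0.02)
})
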