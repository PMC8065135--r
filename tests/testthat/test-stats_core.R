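test_that("bh_fdr matches hand-worked step-up values and contracts", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12) && all(q <= 1))
  # monotone non-decreasing when sorted by p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("two-sample t matches the closed form and its symmetries", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- two_sample_ttest(x, y, "pooled")
  # textbook: sp2 = 1, se = sqrt(2/3), t = -3/sqrt(2/3)
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  swapped <- two_sample_ttest(y, x, "pooled")
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p, res$p)
  same <- two_sample_ttest(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # degenerate contracts
  expect_equal(two_sample_ttest(c(1, 1), c(1, 1))$p, 1)
  expect_warning(res0 <- two_sample_ttest(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(res0$p, 0)
})

test_that("linear model group test equals pooled t without covariates", {
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(9, 0.5)
    grp <- c(rep(0, 8), rep(1, 9))
    lmres <- linear_model_group_test(c(x, y), grp)
    tres <- two_sample_ttest(y, x, "pooled")
    expect_equal(lmres$statistic, tres$statistic, tolerance = 1e-10)
    expect_equal(lmres$p, tres$p, tolerance = 1e-10)
  }
})

test_that("linear model recovers planted effects and flags collinearity", {
  set.seed(3)
  n <- 28
  grp <- rep(0:1, each = n / 2)
  age <- rnorm(n, 56, 7)
  y <- 1.0 * grp + 0.1 * age + rnorm(n, 0, 0.01)
  res <- linear_model_group_test(y, grp, cbind(age = age))
  expect_lt(abs(res$estimate - 1.0), 0.05)
  # y determined by covariate, independent of group
  y2 <- 2 * age + rnorm(n, 0, 0.01)
  res2 <- linear_model_group_test(y2, grp, cbind(age = age))
  expect_lt(abs(res2$estimate), 0.05)
  expect_gt(res2$p, 0.3)
  # duplicated covariate -> named error
  expect_error(
    linear_model_group_test(y, grp, cbind(age = age, age2 = age)),
    "collinear.*age2")
})

test_that("group-test p-values are calibrated under a global null", {
  set.seed(4)
  n <- 28
  grp <- rep(0:1, each = n / 2)
  covs <- cbind(age = rnorm(n, 56, 7), bmi = rnorm(n, 25.7, 3.1),
                sex = rep_len(0:1, n))
  nfeat <- 20000
  p <- vapply(seq_len(nfeat), function(i) {
    linear_model_group_test(rnorm(n), grp, covs)$p
  }, 0)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("wilcoxon signed rank: worked example, symmetry, edge cases", {
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0), mode = "exact")
  expect_equal(res$statistic, 6)
  expect_equal(res$p, 0.25) # 2/8 under full sign enumeration
  neg <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3), mode = "exact")
  expect_equal(neg$p, res$p)
  expect_warning(z <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(z$p, 1)
  # ties use midranks and survive exact mode via doubled ranks
  res_t <- wilcoxon_signed_rank(c(1, 1, 2, 3), c(0, 0, 0, 0), mode = "exact")
  expect_true(res_t$p >= 0 && res_t$p <= 1)
})

test_that("chi-squared matches hand calculation and conventions", {
  res <- chi2_test(matrix(c(10, 90, 30, 70), 2, 2, byrow = TRUE))
  expect_equal(res$statistic, 12.5)
  expect_equal(res$df, 1)
  expect_equal(chi2_test(c(25, 25, 25, 25), "uniform")$statistic, 0)
  same <- chi2_test(c(10, 20, 30), expected = c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(chi2_test(c(0, 0)), "zero-total")
  expect_warning(chi2_test(c(4, 1), expected = c(0.9, 0.1)), "below 1")
})

test_that("correlation test: perfect, rank-invariant and oracle-checked", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(correlation_test(x, -x, "pearson")$statistic, -1)
  expect_equal(correlation_test(x, -x, "spearman")$statistic, -1)
  # monotone nonlinear: spearman 1, pearson < 1
  xm <- 1:10
  ym <- exp(xm)
  expect_equal(correlation_test(xm, ym, "spearman")$statistic, 1)
  expect_lt(correlation_test(xm, ym, "pearson")$statistic, 1)
  # spearman equals pearson on midranks, 20 random draws of n = 14
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(14); b <- rnorm(14)
    sp <- correlation_test(a, b, "spearman")$statistic
    pr <- correlation_test(rank(a), rank(b), "pearson")$statistic
    expect_equal(sp, pr, tolerance = 1e-12)
  }
  expect_warning(res <- correlation_test(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(res$statistic))
})

test_that("PCA: rank-1 dominance, orthogonality, variance conservation", {
  set.seed(7)
  u <- rnorm(30); v <- rnorm(8)
  X <- outer(u, v) + matrix(rnorm(240, 0, 1e-8), 30, 8)
  res <- pca_top_components(X, 3)
  expect_gt(res$explained[1], 0.999)
  expect_lt(abs(sum(res$scores[, 1] * res$scores[, 2])), 1e-6)
  expect_equal(sum(res$explained_all), 1, tolerance = 1e-8)
  expect_error(pca_top_components(matrix(1, 5, 4), 2), "constant")
})
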