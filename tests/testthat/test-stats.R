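# Repeated-measures inference layer against independent oracles.

test_that("RM-ANOVA matches the brute-force decomposition", {
  set.seed(301)
  for (i in 1:5) {
    Y <- matrix(rnorm(54, mean = 50, sd = 8), 9, 6) + rnorm(9, sd = 5)
    fit <- rm_anova_gg(Y)
    orc <- oracle_rm_anova(Y)
    expect_equal(fit$f_stat, orc$f, tolerance = 1e-8)
    expect_equal(fit$ss_condition, orc$ss_cond, tolerance = 1e-8)
    expect_equal(fit$ss_error, orc$ss_err, tolerance = 1e-8)
    expect_equal(fit$partial_eta_sq, orc$eta, tolerance = 1e-8)
    expect_equal(fit$gg_epsilon, orc$eps, tolerance = 1e-8)
    expect_gte(fit$gg_epsilon, 1 / 5)
    ## aov as a second, independent route for the F statistic
    df <- data.frame(y = as.numeric(Y),
                     subj = factor(rep(1:9, 6)), cond = factor(rep(1:6, each = 9)))
    aov_f <- summary(stats::aov(y ~ cond + Error(subj), df))[[2]][[1]]["cond", "F value"]
    expect_equal(fit$f_stat, aov_f, tolerance = 1e-8)
  }
})

test_that("degenerate and small designs behave as theory requires", {
  Y <- matrix(rep(c(3, 7, 1, 9), 4), 4, 4)
  fit <- rm_anova_gg(Y)
  expect_equal(fit$f_stat, 0)
  expect_equal(fit$partial_eta_sq, 0)
  ## k = 2: F equals the squared paired t statistic
  set.seed(302)
  Y2 <- matrix(rnorm(18, 40, 6), 9, 2)
  fit2 <- rm_anova_gg(Y2)
  tt <- stats::t.test(Y2[, 1], Y2[, 2], paired = TRUE)
  expect_equal(fit2$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit2$p_uncorrected, tt$p.value, tolerance = 1e-10)
  expect_equal(fit2$gg_epsilon, 1)
  expect_error(rm_anova_gg(matrix(1:6, 6, 1)), "2 conditions")
  Yna <- matrix(rnorm(12), 4, 3); Yna[2, 2] <- NA
  expect_error(rm_anova_gg(Yna), "complete")
})

test_that("epsilon is exactly 1 for compound-symmetric sample covariance", {
  set.seed(303)
  n <- 12; k <- 4
  X <- scale(matrix(rnorm(n * k), n, k))
  X <- X %*% solve(chol(stats::cov(X)))      # sample covariance = identity
  sigma <- 0.4 + diag(k) * 0.6               # compound symmetry
  Y <- X %*% chol(sigma)
  expect_equal(rm_anova_gg(Y)$gg_epsilon, 1, tolerance = 1e-10)
})

test_that("partial eta squared is invariant to shift and scale", {
  set.seed(304)
  Y <- matrix(rnorm(30, 20, 4), 6, 5)
  e0 <- rm_anova_gg(Y)$partial_eta_sq
  expect_equal(rm_anova_gg(Y + 100)$partial_eta_sq, e0, tolerance = 1e-12)
  expect_equal(rm_anova_gg(Y * 57.3)$partial_eta_sq, e0, tolerance = 1e-12)
})

test_that("LSD post-hoc equals uncorrected pairwise paired t-tests", {
  set.seed(305)
  Y <- matrix(rnorm(54, 30, 5), 9, 6,
              dimnames = list(NULL, pad_conditions()))
  ph <- lsd_posthoc(Y)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(ph$p_value[i, j], oracle_paired_t_p(Y[, i], Y[, j]),
                 tolerance = 1e-10)
    expect_equal(ph$p_value[j, i], ph$p_value[i, j])
    expect_equal(ph$mean_diff[i, j], -ph$mean_diff[j, i])
  }
  expect_true(all(is.na(diag(ph$p_value))))
  ## identical columns: t = 0, p = 1 exactly
  Y[, 2] <- Y[, 1]
  expect_equal(lsd_posthoc(Y)$p_value[1, 2], 1)
})

test_that("effect-size bands follow the stated thresholds", {
  expect_identical(classify_eta_sq(0.05), "small")
  expect_identical(classify_eta_sq(0.06), "medium")
  expect_identical(classify_eta_sq(0.14), "large")
  expect_identical(classify_eta_sq(0.005), "below_small")
  expect_error(classify_eta_sq(1.2), "\\[0, 1\\]")
})

test_that("Friedman test matches the tie-corrected rank formula", {
  m0 <- matrix(rep(c(2, 4, 4, 5, 1, 3, 2, 2, 3), 4), 9, 4)
  res0 <- friedman_test(m0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  set.seed(306)
  for (i in 1:5) {
    m <- matrix(sample(1:5, 45, replace = TRUE), 9, 5)
    if (all(apply(m, 1, function(r) diff(range(r)) == 0))) next
    res <- friedman_test(m)
    orc <- oracle_friedman(m)
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-8)
    expect_equal(res$p_value, orc$p, tolerance = 1e-8)
  }
  ## strictly monotone columns attain the maximum for the shape
  mono <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  got <- friedman_test(mono)$statistic
  perms3 <- gtools_perms(3)
  all_stats <- apply(as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6)), 1, function(idx) {
    m <- t(vapply(idx, function(r) perms3[r, ], numeric(3)))
    oracle_friedman(m)$statistic
  })
  expect_equal(got, max(all_stats), tolerance = 1e-8)
  expect_error(friedman_test(cbind(1:5)), "2 conditions")
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(307)
  m <- matrix(sample(1:5, 27, replace = TRUE), 9, 3)
  f <- function(x) exp(x) + x^3
  if (!all(apply(m, 1, function(r) diff(range(r)) == 0))) {
    expect_equal(friedman_test(m)$statistic, friedman_test(f(m))$statistic,
                 tolerance = 1e-10)
  }
  ## the signed-rank statistic ranks |a - b|, so it is invariant under
  ## positive affine transforms (a general monotone transform can reorder
  ## the absolute differences)
  a <- c(5, 3, 4, 1, 2, 5, 4, 2, 1); b <- c(2, 4, 1, 3, 5, 1, 2, 4, 3)
  expect_equal(wilcoxon_signed_rank(a, b)$statistic,
               wilcoxon_signed_rank(2 * a + 7, 2 * b + 7)$statistic)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_corr(x, y)$rho, spearman_corr(f(x), f(y))$rho,
               tolerance = 1e-12)
  expect_equal(spearman_corr(x, y)$rho, spearman_corr(y, x)$rho)
})

test_that("Wilcoxon signed-rank matches full enumeration", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  res1 <- wilcoxon_signed_rank(c(3, 3, 3), c(3, 3, 2))
  expect_equal(res1$p_value, 1)
  expect_equal(res1$n_used, 1)
  set.seed(308)
  for (i in 1:5) {
    a <- sample(1:5, 9, replace = TRUE)
    b <- sample(1:5, 9, replace = TRUE)
    if (all(a == b)) next
    res <- wilcoxon_signed_rank(a, b)
    expect_equal(res$p_value, oracle_wilcoxon_exact(a - b), tolerance = 1e-12)
  }
  ## tie-free case agrees with the exact reference implementation
  a <- c(1.2, 0.4, -2.1, 3.3, 0.9, -1.5, 2.2, 0.1)
  b <- rep(0, 8)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Spearman correlation matches enumeration and endpoints", {
  expect_equal(spearman_corr(1:6, c(2, 5, 7, 8, 12, 20))$rho, 1)
  expect_equal(spearman_corr(1:6, 6:1)$rho, -1)
  set.seed(309)
  for (i in 1:4) {
    x <- sample(100, 5); y <- sample(100, 5)
    res <- spearman_corr(x, y)
    orc <- oracle_spearman(x, y)
    expect_equal(res$rho, orc$rho, tolerance = 1e-12)
    expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  }
  expect_error(spearman_corr(rep(2, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("correlation bands follow the stated thresholds", {
  expect_identical(classify_correlation(0.975), "high")
  expect_identical(classify_correlation(0.35), "moderate")
  expect_identical(classify_correlation(-0.2), "low")
  expect_identical(classify_correlation(0.05), "negligible")
  expect_error(classify_correlation(1.2), "<= 1")
})

test_that("Shapiro-Wilk screen behaves on normal and degenerate input", {
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  expect_error(shapiro_wilk(1:2), "3 <= n")
  sym <- c(1, 2, 3, 4, 3, 2, 1)
  expect_gt(shapiro_wilk(sym)$statistic, 0.9)
  set.seed(310)
  hits <- mean(replicate(30, shapiro_wilk(rnorm(100))$p_value > 0.05))
  expect_gte(hits, 0.9)
})
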