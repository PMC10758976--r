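## Repeated-measures inference layer: normality screening, one-way
## repeated-measures ANOVA with Greenhouse-Geisser correction, LSD post-hoc
## comparisons, effect-size bands, and the non-parametric survey tests.

check_condition_matrix <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("condition matrix must be complete (no missing cells)")
  if (ncol(values) < 2L) stop("need at least 2 conditions")
  if (nrow(values) < 2L) stop("need at least 2 participants")
  values
}

#' Shapiro-Wilk normality test
#'
#' Screens ROM samples for normality before the parametric analyses.
#' Delegates to the standard published algorithm in [stats::shapiro.test()].
#'
#' @param values Numeric sample, 3 <= n <= 5000, not constant.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  if (!is.numeric(values) || anyNA(values)) stop("values must be numeric, no NA")
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0) stop("W is undefined for a constant sample")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

## Mauchly's sphericity test on the orthonormal-contrast covariance.
## Returns NA when the contrast covariance is singular (n - 1 < k - 1).
mauchly_sphericity_p <- function(values) {
  n <- nrow(values); k <- ncol(values)
  p_ <- k - 1L
  if (n - 1L < p_) return(NA_real_)
  C <- t(qr.Q(qr(cbind(1, diag(k)[, -k])))[, -1L])
  Z <- values %*% t(C)
  S <- stats::cov(Z)
  dt <- det(S)
  tr <- sum(diag(S))
  if (dt <= 0 || tr <= 0) return(NA_real_)
  W <- dt / (tr / p_)^p_
  d <- n - 1L
  f <- 1 - (2 * p_^2 + p_ + 2) / (6 * p_ * d)
  chi <- -f * d * log(W)
  stats::pchisq(chi, p_ * (p_ + 1) / 2 - 1, lower.tail = FALSE)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject decomposition of a participants x conditions matrix into
#' condition, subject and error sums of squares.  The Greenhouse-Geisser
#' epsilon is estimated from the double-centered sample covariance of the
#' conditions and bounded in `[1/(k-1), 1]`; partial eta-squared is
#' `SS_cond / (SS_cond + SS_err)`.
#'
#' The sphericity correction policy is configurable:
#' * `"mauchly"` (default): the Greenhouse-Geisser corrected p-value is used
#'   when Mauchly's test rejects sphericity at `gate_alpha`, otherwise the
#'   uncorrected p-value — the common repeated-measures workflow, and the one
#'   whose type-I error stays near the nominal level for small samples
#'   (always-on correction is markedly conservative when sphericity actually
#'   holds; see the methods vignette).
#' * `"always"`: the corrected p-value is always reported.
#' * `"never"`: the uncorrected p-value is reported.
#'
#' Both corrected and uncorrected p-values are returned regardless of policy.
#'
#' @param values Numeric matrix, participants in rows, conditions in columns,
#'   complete.
#' @param sphericity Correction policy, see above.
#' @param gate_alpha Significance level of the Mauchly gate (default 0.05).
#' @return Object of class `rm_anova_result`: `f_stat`, `df_effect`,
#'   `df_error` (corrected when the policy corrects), `p_value`,
#'   `p_uncorrected`, `p_gg`, `gg_epsilon`, `mauchly_p`, `partial_eta_sq`,
#'   and the sums of squares `ss_condition`, `ss_subject`, `ss_error`.
#' @export
rm_anova_gg <- function(values, sphericity = c("mauchly", "always", "never"),
                        gate_alpha = 0.05) {
  sphericity <- match.arg(sphericity)
  values <- check_condition_matrix(values)
  n <- nrow(values); k <- ncol(values)
  gm <- mean(values)
  cm <- colMeans(values); rm_ <- rowMeans(values)
  ss_cond <- n * sum((cm - gm)^2)
  ss_subj <- k * sum((rm_ - gm)^2)
  ss_err <- sum((values - gm)^2) - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  f_stat <- if (ms_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / df1) / ms_err
  ## Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(values)
  C <- diag(k) - 1 / k
  St <- C %*% S %*% C
  denom <- (k - 1) * sum(St^2)
  eps <- if (denom <= 0) 1 else sum(diag(St))^2 / denom
  eps <- min(1, max(1 / (k - 1), eps))
  p_unc <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  mau <- mauchly_sphericity_p(values)
  corrected <- switch(sphericity,
    always = TRUE,
    never = FALSE,
    mauchly = !is.na(mau) && mau < gate_alpha)
  structure(list(
    f_stat = f_stat,
    df_effect = if (corrected) eps * df1 else df1,
    df_error = if (corrected) eps * df2 else df2,
    p_value = if (corrected) p_gg else p_unc,
    p_uncorrected = p_unc, p_gg = p_gg,
    gg_epsilon = eps, mauchly_p = mau, corrected = corrected,
    partial_eta_sq = if (ss_cond + ss_err == 0) 0
                     else ss_cond / (ss_cond + ss_err),
    ss_condition = ss_cond, ss_subject = ss_subj, ss_error = ss_err,
    n = n, k = k
  ), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf(
    "RM-ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g (GG eps = %.3f%s), eta_p^2 = %.3f\n",
    x$df_effect, x$df_error, x$f_stat, x$p_value, x$gg_epsilon,
    if (x$corrected) ", corrected" else ", uncorrected", x$partial_eta_sq))
  invisible(x)
}

#' Least-significant-difference post-hoc comparisons
#'
#' Uncorrected pairwise paired t-tests over all condition pairs (the LSD
#' procedure: no multiplicity adjustment beyond gating on a significant
#' omnibus test, which is the caller's responsibility).  A pair with
#' identical columns has t = 0 and p = 1.
#'
#' @param values Participants x conditions matrix, complete.
#' @return List of two k x k matrices: `p_value` (symmetric, `NA` diagonal)
#'   and `mean_diff` (row condition minus column condition, degrees).
#' @export
lsd_posthoc <- function(values) {
  values <- check_condition_matrix(values)
  k <- ncol(values)
  labs <- colnames(values)
  if (is.null(labs)) labs <- paste0("cond", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  d <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      diffs <- values[, i] - values[, j]
      d[i, j] <- mean(diffs); d[j, i] <- -mean(diffs)
      pij <- if (stats::sd(diffs) == 0) {
        if (mean(diffs) == 0) 1 else 0
      } else {
        stats::t.test(values[, i], values[, j], paired = TRUE)$p.value
      }
      p[i, j] <- pij; p[j, i] <- pij
    }
  }
  list(p_value = p, mean_diff = d)
}

#' Classify a partial eta-squared effect size
#'
#' Bands: below 0.01 is flagged `below_small`; `[0.01, 0.06)` small,
#' `[0.06, 0.14)` medium, `>= 0.14` large.
#'
#' @param eta Partial eta-squared in `[0, 1]`.
#' @return One of `"below_small"`, `"small"`, `"medium"`, `"large"`.
#' @export
classify_eta_sq <- function(eta) {
  if (!is.finite(eta) || eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  if (eta < 0.01) "below_small"
  else if (eta < 0.06) "small"
  else if (eta < 0.14) "medium"
  else "large"
}

#' Friedman rank test for related ordinal samples
#'
#' Rank-based omnibus test across pad conditions for survey scores, with
#' average-rank tie handling and a chi-square reference distribution.
#' Delegates to [stats::friedman.test()].
#'
#' @param scores Participants x conditions matrix of ordinal scores,
#'   complete.
#' @return List with `statistic` (chi-square), `df` and `p_value`.
#' @export
friedman_test <- function(scores) {
  scores <- check_condition_matrix(scores)
  if (all(apply(scores, 1L, function(r) diff(range(r)) == 0))) {
    ## every row fully tied: no rank information, statistic degenerates to 0
    return(list(statistic = 0, df = ncol(scores) - 1, p_value = 1))
  }
  ht <- stats::friedman.test(as.matrix(scores))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

## Exact null distribution of the doubled positive-rank sum given the
## (possibly tied, average) absolute ranks: subset-sum counting over sign
## assignments.
wilcoxon_exact_p <- function(w_obs, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2W = s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * w_obs))
  lo <- sum(counts[seq_len(w2 + 1L)])                  # P(2W <= w2) * 2^n
  hi <- sum(counts[seq(w2 + 1L, total + 1L)])          # P(2W >= w2) * 2^n
  min(1, 2 * min(lo, hi) / 2^length(r2))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the classical treatment) and tied absolute
#' differences receive average ranks.  The p-value is exact — computed from
#' the full null distribution of the positive-rank sum given the observed
#' ranks — for `n <= exact_limit` non-zero pairs, and uses the
#' tie-corrected normal approximation above that.
#'
#' @param a,b Paired numeric samples of equal length.
#' @param exact_limit Largest n for the exact p-value (default 25).
#' @return List with `statistic` (positive-rank sum W), `n_used` (non-zero
#'   pairs) and `p_value` (two-sided).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: no information")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- wilcoxon_exact_p(W, r)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, n_used = n, p_value = min(1, p))
}

## All permutations of 1..n (n small), rows = permutations.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(pos) {
    left <- if (pos > 1L) sub[, seq_len(pos - 1L), drop = FALSE] else NULL
    right <- if (pos < n) sub[, seq(pos, n - 1L), drop = FALSE] else NULL
    cbind(left, n, right)
  })
  do.call(rbind, blocks)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks.  The two-sided p-value is exact —
#' by enumeration over all permutations of one rank vector — for
#' `n <= exact_limit`, and uses the t approximation with `n - 2` degrees of
#' freedom above that.
#'
#' @param x,y Numeric samples of equal length, n >= 3, neither constant.
#' @param exact_limit Largest n for the exact permutation p-value (default 8).
#' @return List with `rho` and `p_value`.
#' @export
spearman_corr <- function(x, y, exact_limit = 8) {
  if (length(x) != length(y)) stop("samples must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("correlation undefined for a constant sample")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- all_permutations(n)
    cx <- rx - mean(rx)
    cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rhos <- as.numeric(matrix(cy[perms], nrow(perms)) %*% cx) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p_value = min(1, p))
}

#' Classify a correlation coefficient
#'
#' Bands on `|r|`: below 0.1 is flagged `negligible`; `[0.1, 0.3)` low,
#' `[0.3, 0.5)` moderate, `[0.5, 1]` high.
#'
#' @param r Correlation coefficient, `|r| <= 1`.
#' @return One of `"negligible"`, `"low"`, `"moderate"`, `"high"`.
#' @export
classify_correlation <- function(r) {
  if (!is.finite(r) || abs(r) > 1) stop("|r| must be <= 1")
  a <- abs(r)
  if (a < 0.1) "negligible"
  else if (a < 0.3) "low"
  else if (a < 0.5) "moderate"
  else "high"
}
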