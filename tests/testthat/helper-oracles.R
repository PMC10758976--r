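# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package implementation: rotation
# matrices instead of quaternion algebra, explicit sums-of-squares and
# eigenvalue formulas for the ANOVA, enumeration for the exact tests.

## rotation matrix about a principal axis, degrees
rot_mat <- function(axis, deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

## rotation matrix from a scalar-first quaternion (textbook formula)
rmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, byrow = TRUE)
}

## geodesic angle (degrees) between two unit quaternions, sign-insensitive
quat_angle_deg <- function(a, b) {
  2 * acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

random_unit_quats <- function(n) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

## brute-force within-subject ANOVA decomposition (cell-by-cell loops) with
## eigenvalue-based Greenhouse-Geisser epsilon
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(Y[, j]) - gm)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(Y[i, ]) - gm)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (Y[i, j] - gm)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  C <- diag(k) - 1 / k
  lam <- eigen(C %*% stats::cov(Y) %*% C, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err, f = f,
       eta = ss_cond / (ss_cond + ss_err), eps = min(1, eps))
}

## paired t-test p-value from the textbook formula
oracle_paired_t_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_ <- mean(d) / (stats::sd(d) / sqrt(n))
  2 * stats::pt(-abs(t_), n - 1)
}

## tie-corrected Friedman chi-square from explicit within-row ranks
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  chi <- num / den
  list(statistic = chi, p = stats::pchisq(chi, k - 1, lower.tail = FALSE))
}

## exact two-sided Wilcoxon signed-rank p by full enumeration over the 2^n
## sign assignments (zeros already dropped by the caller)
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

## Spearman rho via the classic 6*sum(d^2) formula (tie-free inputs only)
## and exact permutation p by full enumeration
oracle_spearman <- function(x, y) {
  n <- length(x)
  rho_of <- function(rx, ry) 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  rx <- rank(x); ry <- rank(y)
  rho <- rho_of(rx, ry)
  perms <- gtools_perms(n)
  rhos <- apply(perms, 1, function(p) rho_of(rx, ry[p]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

## all permutations of 1..n, plain recursion
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

## a small, fast generator configuration for pipeline tests
tiny_config <- function(seed = 11, ...) {
  generator_config(n_participants = 2, repetitions = 1,
                   tasks = c("sho_flex", "elb_flex", "wrist_shot"),
                   conditions = c("no_pads", "vik_max"),
                   handedness = c("left", "right"), seed = seed, ...)
}

## identity-orientation trial for degenerate-input tests
constant_trial <- function(task = "wrist_shot", n = 300) {
  ident <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
  segs <- stats::setNames(lapply(upper_body_segments(), function(s) ident),
                          upper_body_segments())
  trial_recording("P01", "no_pads", task, 1, "left", segs)
}
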