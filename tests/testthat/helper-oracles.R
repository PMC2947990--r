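# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the stats functions) used by the implementation.

# one-sided exact signed-rank p for H1: differences > 0, by enumerating all
# 2^n sign assignments of the ranked absolute differences (no ties assumed)
bf_signed_rank_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

# two-sided rank-sum p by enumerating all group assignments
bf_ranksum_two_sided <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  splits <- combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(i) sum(r[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# two-sided (doubled smaller tail) hypergeometric p by pmf summation
bf_hyper_two_sided <- function(k, K, N, n) {
  kk <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  lower <- sum(pmf[kk <= k])
  upper <- sum(pmf[kk >= k])
  min(1, 2 * min(lower, upper))
}

# central two-sided exact binomial p by density summation (the binom.test
# definition, recomputed from scratch)
bf_binom_central <- function(x, n, p) {
  dd <- dbinom(0:n, n, p)
  sum(dd[dd <= dbinom(x, n, p) * (1 + 1e-7)])
}

# two-sample KS statistic as the max gap between empirical CDFs,
# evaluated over all data points
bf_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), 0)
  Fy <- vapply(pts, function(t) mean(y <= t), 0)
  max(abs(Fx - Fy))
}

# textbook pooled-variance two-sample t (scalar, no vectorization tricks)
bf_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}
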