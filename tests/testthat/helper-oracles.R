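# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (loops, full enumeration) and share no code with the
# package implementation.

# per-channel optical density, scalar arithmetic
oracle_od_pixel <- function(rgb, i0 = 255, eps = 1) {
  sapply(seq_along(rgb), function(c) -log10(max(rgb[c], eps) / i0))
}

# cross product via the cofactor formula, then normalise
oracle_unit_cross <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  v / sqrt(sum(v^2))
}

# per-pixel 3x3 linear solve (no clamping)
oracle_unmix_pixel <- function(od, m) as.numeric(solve(t(m), od))

# all-pairs ROC AUC count
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon signed-rank p-value by enumerating all sign
# assignments (assumes no zeros and no tied absolute differences)
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  min(1, p)
}

# exact two-sided Mann-Whitney p-value by enumerating all group assignments
# (assumes no ties across the pooled sample)
oracle_mann_whitney_p <- function(g1, g2) {
  stopifnot(!any(duplicated(c(g1, g2))))
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# 1-D grid search maximiser of the Cox partial likelihood for a single
# binary covariate
oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5, tol = 1e-6) {
  loglik <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

# discretised annulus pixel count around a disc of radius r
oracle_annulus_area <- function(r, w, grid = 101) {
  cx <- (grid + 1) / 2
  cnt <- 0
  for (i in seq_len(grid)) for (j in seq_len(grid)) {
    d <- sqrt((i - cx)^2 + (j - cx)^2)
    if (d > r && d <= r + w) cnt <- cnt + 1
  }
  cnt
}
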