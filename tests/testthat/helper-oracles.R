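# Independent naive oracles used to cross-check the implementation. These are
# deliberately written from first principles, not by calling the functions
# they verify.

# Triangle membership by explicit barycentric coordinates (solve a 2x2
# system), boundary inclusive.
oracle_in_triangle <- function(px, py, v) {
  Tm <- cbind(v[2, ] - v[1, ], v[3, ] - v[1, ])
  lam <- solve(Tm, c(px - v[1, 1], py - v[1, 2]))
  eps <- 1e-9
  lam[1] >= -eps && lam[2] >= -eps && sum(lam) <= 1 + eps
}

# Median by sorting.
oracle_median <- function(x) {
  x <- sort(x); n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Outlier decisions under the median + k*MAD rule with the degenerate
# MAD = 0 branch (strict excess over the median).
oracle_mad_outliers <- function(d, k = 3, cc = 1.4826) {
  med <- oracle_median(d)
  mad <- cc * oracle_median(abs(d - med))
  thr <- med + k * mad
  list(threshold = thr,
       outlier = if (mad == 0) d > med else d >= thr)
}

# Holm step-down adjustment, literal definition.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Bland-Altman with an explicit sum-of-squares SD (n-1 denominator).
oracle_bland_altman <- function(d, z = 1.96) {
  n <- length(d); m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  c(mean = m, sd = s, lo = m - z * s, hi = m + z * s)
}
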