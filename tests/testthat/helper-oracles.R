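# Shared oracles and small builders used across test files.

# Exhaustive-enumeration oracle for the exact two-sided Wilcoxon rank-sum
# p-value: enumerate every relabeling of the pooled sample into groups of
# sizes (n1, n2) and count rank sums at least / at most as extreme.
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  Ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_hi <- mean(Ws >= W_obs)
  p_lo <- mean(Ws <= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force epoch counter: slide the window sample-free, in seconds.
count_windows <- function(duration, window, step) {
  k <- 0
  start <- 0
  while (start + window <= duration + 1e-9) {
    k <- k + 1
    start <- start + step
  }
  k
}

# Hand implementation of the Benjamini-Hochberg step-up adjustment.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# A minimal single-stream recording for pipeline tests.
one_stream_recording <- function(id, s, gad_pre = rep(1, 7), gad_post = rep(2, 7)) {
  recording(id, stats::setNames(list(s), s$name), gad_pre, gad_post)
}
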