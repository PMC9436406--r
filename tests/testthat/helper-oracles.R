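# Independent oracles, coded separately from the package internals.

# Exact two-sided signed-rank p by looping over all 2^n sign masks (bit by
# bit, no matrix algebra), doubling the smaller tail and capping at 1.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 2^n
  w_all <- numeric(total)
  for (mask in 0:(total - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    w_all[mask + 1] <- sum(r[bits == 1L])
  }
  p_le <- sum(w_all <= w_obs + 1e-9) / total
  p_ge <- sum(w_all >= w_obs - 1e-9) / total
  min(1, 2 * min(p_le, p_ge))
}

# Direct step-up Benjamini-Hochberg: adj_(i) = min_{j >= i} m * p_(j) / j,
# capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Friedman chi-square recomputed from first principles for one matrix
# (midranks, tie correction from the rank tie groups).
oracle_friedman_chi2 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  tie_term <- 0
  for (i in seq_len(n)) {
    for (t in table(r[i, ])) tie_term <- tie_term + (t^3 - t)
  }
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(0)
  12 * sum((rj - n * (k + 1) / 2)^2) / denom
}
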