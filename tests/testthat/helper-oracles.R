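# Independent oracles, deliberately written with different machinery than
# the implementation they check.

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  na <- length(x)
  r <- rank(c(x, y))
  combos <- utils::combn(length(r), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  mu <- mean(sums)
  obs <- sum(r[seq_len(na)])
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# signed absolute extremum by explicit case analysis
oracle_aggregate <- function(v) {
  m <- max(abs(v))
  cand <- v[abs(v) == m]
  if (any(cand > 0)) max(cand) else min(cand)
}

# density-crossing root of the count-weighted two-Gaussian objective
oracle_crossing <- function(mu_c, sd_c, n_c, mu_s, sd_s, n_s) {
  f <- function(t) n_c * dnorm(t, mu_c, sd_c) - n_s * dnorm(t, mu_s, sd_s)
  uniroot(f, lower = mu_c, upper = mu_s, tol = 1e-12)$root
}

# rescale a sample to exact first and second moments
with_moments <- function(x, mu, s) mu + (x - mean(x)) / sd(x) * s
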