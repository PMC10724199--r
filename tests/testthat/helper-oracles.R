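# Independent brute-force oracles. These deliberately avoid the code paths
# they check: enumeration and double loops only.

# P(overlap >= k) by exhaustive enumeration of all C(N, n) draws
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)          # items 1..K are the "successes"
  mean(hits >= k)
}

# two-sided Fisher p for a 2x2 table by full-margin enumeration, using the
# standard "sum of all tables at most as probable" definition
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(xs, m, n, k)
  d_obs <- stats::dhyper(x_obs, m, n, k)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# signed max CDF difference by a double loop over all observed thresholds
oracle_ks_signed <- function(xs, xb) {
  thr <- sort(unique(c(xs, xb)))
  best <- 0
  for (t in thr) {
    diff <- mean(xb <= t) - mean(xs <= t)
    if (abs(diff) > abs(best)) best <- diff
  }
  best
}

# percentile-band gene filter by brute force under the package's stated
# convention (type-4 quantiles, inclusive bounds)
oracle_filter_keep <- function(totals, lo, hi) {
  qs <- stats::quantile(totals, c(lo, hi) / 100, type = 4, names = FALSE)
  names(totals)[totals >= qs[1] & totals <= qs[2]]
}
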