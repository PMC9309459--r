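# Independent oracles kept deliberately naive (scalar loops, dense grids)
# so they share no code path with the package implementation.

# Weir & Cockerham (1984) two-population variance components for one SNP,
# transcribed directly from the per-locus ANOVA definitions.
wc84_oracle_snp <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- sum(gA == 1) / n1;  h2 <- sum(gB == 1) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc),
       pooled_mono = pbar <= 0 || pbar >= 1)
}

# Exact hypergeometric upper tail P(X >= k) by direct log-binomial sums.
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  if (!length(i) || k > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Dense-trapezoid integration of the censored-Normal x binomial likelihood
# pieces used by the scan, on `ngrid` points, plus boundary point masses.
tn_binom_trapezoid <- function(mu, sd, k2, n2, ngrid = 10000) {
  if (sd <= 0) return(dbinom(k2, n2, min(1, max(0, mu))))
  x <- seq(0, 1, length.out = ngrid)
  f <- dnorm(x, mu, sd) * dbinom(k2, n2, x)
  int <- sum((f[-1] + f[-ngrid]) / 2) * (x[2] - x[1])
  int + pnorm(0, mu, sd) * dbinom(k2, n2, 0) +
    pnorm(1, mu, sd, lower.tail = FALSE) * dbinom(k2, n2, 1)
}

snp_loglik_oracle <- function(p1, k2, n2, omega, c, resid_frac = 0.05,
                              ngrid = 10000) {
  v <- p1 * (1 - p1)
  neu <- tn_binom_trapezoid(p1, sqrt(omega * v), k2, n2, ngrid)
  sdf <- sqrt(resid_frac * omega * v)
  hh <- p1 * tn_binom_trapezoid(1, sdf, k2, n2, ngrid) +
    (1 - p1) * tn_binom_trapezoid(0, sdf, k2, n2, ngrid)
  list(neutral = log(neu), selected = log((1 - c) * hh + c * neu))
}

# Hand percentile: linear interpolation between order statistics
# (h = 1 + q(n-1)).
percentile_oracle <- function(x, q) {
  x <- sort(x[!is.na(x)])
  h <- 1 + (q / 100) * (length(x) - 1)
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
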