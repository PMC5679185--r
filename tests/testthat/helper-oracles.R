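# Independent brute-force oracles: deliberately naive implementations
# written from the definitions, used only to cross-check the package.

# linear interpolation of order statistics, written out by hand
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  frac <- h - lo
  x[lo + 1] * (1 - frac) + ifelse(frac > 0, x[lo + 2] * frac, 0)
}

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_iqr <- function(x) oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25)

oracle_p30 <- function(mgfr, egfr) {
  hits <- 0
  for (i in seq_along(mgfr))
    if (abs(egfr[i] - mgfr[i]) <= 0.30 * mgfr[i]) hits <- hits + 1
  hits / length(mgfr)
}

# exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (valid for distinct non-zero |z|); mirrors the symmetric
# two-tail convention p = min(1, 2 * min(P(W <= w), P(W >= w)))
oracle_wilcoxon_exact <- function(z) {
  n <- length(z)
  r <- rank(abs(z))
  w_obs <- sum(r[z > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided McNemar p: symmetric binomial tail at p = 1/2
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- seq(0, n)
  prob <- dbinom(k, n, 0.5)
  sum(prob[abs(k - n / 2) >= abs(b - n / 2) - 1e-12])
}
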