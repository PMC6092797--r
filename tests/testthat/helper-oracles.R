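# Independent brute-force oracles, written from the definitions and kept
# separate from the implementation paths they check.

# Two-sided Fisher p by exhaustive enumeration over the hypergeometric
# support, probabilities from log binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; k <- a + c; n <- a + b + c + d
  if (m1 == 0 || k == 0 || m1 == n || k == n) return(1)
  support <- max(0, k - (n - m1)):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(n - m1, k - support) - lchoose(n, k)
  probs <- exp(logp)
  pobs <- exp(lchoose(m1, a) + lchoose(n - m1, k - a) - lchoose(n, k))
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Upper-tail hypergeometric by direct summation of binomial-coefficient terms.
oracle_hyper_tail <- function(population, successes, draws, observed) {
  hi <- min(successes, draws)
  if (observed > hi) return(0)
  ks <- observed:hi
  sum(exp(lchoose(successes, ks) + lchoose(population - successes, draws - ks) -
            lchoose(population, draws)))
}

# Full upper-tail vector for all observed values 0..min(K, n) at once
# (reverse cumulative sum of the pmf).
oracle_hyper_tail_all <- function(population, successes, draws) {
  ks <- 0:min(successes, draws)
  pmf <- exp(lchoose(successes, ks) +
               lchoose(population - successes, draws - ks) -
               lchoose(population, draws))
  rev(cumsum(rev(pmf)))
}

# Poisson upper tail by direct series summation in log space.
oracle_pois_tail <- function(lambda, k) {
  if (k == 0) return(1)
  upper <- max(k + 60, ceiling(lambda + 40 * sqrt(lambda) + 60))
  is <- k:upper
  sum(exp(is * log(lambda) - lambda - lgamma(is + 1)))
}

# Hand step-up BH computation.
oracle_bh <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
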