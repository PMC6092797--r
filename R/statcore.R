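#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value as the sum of probabilities of all tables
#' with the same margins whose hypergeometric probability does not exceed that
#' of the observed table (the convention used by [stats::fisher.test()]).
#' Probabilities are evaluated with [stats::dhyper()] over the full support of
#' the first cell, with the standard relative-error guard for ties.
#'
#' @param a,b,c,d Non-negative integer counts; the table is
#'   `rbind(c(a, b), c(c, d))`.
#' @return A single p-value in (0, 1]. The degenerate all-zero-margin table
#'   returns 1.
#' @examples
#' fisher_exact_two_sided(5, 0, 0, 5)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts)) || any(!is.finite(counts))) {
    stop("counts must be non-negative integers")
  }
  m1 <- a + b # row 1 margin
  k <- a + c  # column 1 margin
  n <- a + b + c + d
  if (m1 == 0L || k == 0L || m1 == n || k == n) {
    return(1)
  }
  support <- max(0L, k - (n - m1)):min(k, m1)
  probs <- dhyper(support, m1, n - m1, k)
  p_obs <- dhyper(a, m1, n - m1, k)
  # relative-error guard against floating-point ties (as in stats::fisher.test)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, max(p, 0))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= observed) where X counts successes among `draws` draws without
#' replacement from a population containing `successes` successes. Used for
#' overlap and gene-set enrichment tests; evaluated in log space by
#' [stats::phyper()] so extreme tails (below 1e-300) remain finite.
#'
#' @param population Population size.
#' @param successes Number of successes in the population.
#' @param draws Number of draws.
#' @param observed Observed number of successes among the draws.
#' @param log_p Return the natural-log probability instead.
#' @return The tail probability (or its log).
#' @examples
#' hypergeom_upper_tail(20, 5, 5, 2)
#' @export
hypergeom_upper_tail <- function(population, successes, draws, observed,
                                 log_p = FALSE) {
  stopifnot(length(population) == 1, length(observed) == 1)
  bad <- successes > population || draws > population ||
    observed > min(successes, draws) || observed < 0 ||
    any(c(population, successes, draws, observed) < 0)
  if (bad) stop("inconsistent hypergeometric counts")
  lp <- phyper(observed - 1, successes, population - successes, draws,
               lower.tail = FALSE, log.p = TRUE)
  if (log_p) lp else exp(lp)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed; NA stays NA and
#'   is not counted in the family size).
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Upper-tail Poisson probability
#'
#' P(X >= k) for X ~ Poisson(rate), computed in log space so deep tails stay
#' finite. This is the per-height null used by the peak caller.
#'
#' @param rate Positive Poisson mean.
#' @param k Non-negative integer count.
#' @param log_p Return the natural-log probability instead.
#' @return Tail probability (or its log). Vectorised over `k`.
#' @export
poisson_upper_tail <- function(rate, k, log_p = FALSE) {
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (any(k < 0)) stop("k must be non-negative")
  lp <- ppois(k - 1, rate, lower.tail = FALSE, log.p = TRUE)
  if (log_p) lp else exp(lp)
}

#' Chi-squared goodness-of-fit test for a binary split
#'
#' One-degree-of-freedom goodness-of-fit of an observed (success, failure)
#' pair against an expected success proportion, without continuity correction
#' by default. Used for the category-concordance comparison of directional
#' gene counts against the global proportion.
#'
#' @param observed Integer vector of length 2: successes and failures.
#' @param expected_proportion Expected success probability, strictly inside
#'   (0, 1).
#' @param correct Apply Yates' continuity correction.
#' @return The p-value.
#' @export
chi_squared_gof <- function(observed, expected_proportion, correct = FALSE) {
  stopifnot(length(observed) == 2)
  if (sum(observed) <= 0) stop("total count must be positive")
  if (expected_proportion <= 0 || expected_proportion >= 1) {
    stop("expected_proportion must be strictly inside (0, 1)")
  }
  expected <- sum(observed) * c(expected_proportion, 1 - expected_proportion)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  pchisq(statistic, df = 1, lower.tail = FALSE)
}
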