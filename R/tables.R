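# 2x2 contingency tests and Benjamini-Hochberg adjustment, implemented
# directly from their definitions.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by point-probability summation: conditioning on the
#' margins, p is the sum of hypergeometric probabilities of all tables
#' whose point probability does not exceed that of the observed table
#' (relative tolerance 1e-7 on the comparison).
#'
#' @param a,b,c_,d Cell counts of the table `rbind(c(a, b), c(c_, d))`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(0, 21, 7, 14)
fisher_exact_2x2 <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_domain("cell counts must be non-negative integers")
  }
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  if (m1 + m2 == 0 || (k == 0 && (b + d) == 0)) {
    abort_domain("at least one margin must be positive")
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Pearson chi-square test for a 2x2 table
#'
#' Statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` without continuity
#' correction, referred to chi-square with 1 degree of freedom.
#'
#' @inheritParams fisher_exact_2x2
#' @return Tibble with columns `statistic`, `p.value`.
#' @export
chi_square_2x2 <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0)) abort_domain("cell counts must be non-negative")
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    abort_domain("all margins must be positive for the chi-square test")
  }
  n <- sum(counts)
  stat <- n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
  tibble(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare a 2x2 table choosing Fisher or chi-square by expected counts
#'
#' Uses Fisher's exact test when any expected cell count is below 5,
#' otherwise the Pearson chi-square test.
#'
#' @inheritParams fisher_exact_2x2
#' @return Tibble with columns `p.value`, `method`.
#' @export
compare_counts_2x2 <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  n <- a + b + c_ + d
  expected <- outer(c(r1, r2), c(c1, c2)) / n
  if (any(expected < 5) || any(c(r1, r2, c1, c2) == 0)) {
    tibble(p.value = fisher_exact_2x2(a, b, c_, d), method = "fisher")
  } else {
    tibble(p.value = chi_square_2x2(a, b, c_, d)$p.value,
           method = "chi-square")
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: for sorted `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min over j >= i of (m * p_(j) / j)` capped at 1, mapped back
#' to the input order. Tied p-values receive equal q-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
#' @examples
#' adjust_bh(c(0.004, 0.012, 0.018))
adjust_bh <- function(p) {
  if (length(p) < 1) abort_domain("need at least one p-value")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort_domain("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  pmin(1, q_sorted)[order(ord)]
}
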