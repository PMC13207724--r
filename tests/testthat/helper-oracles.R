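# Independent brute-force oracles. These deliberately avoid the code
# paths of the package implementations they check.

# Mann-Whitney oracle: U by direct pair counting, exact two-sided p by
# enumerating every labeling of the pooled sample.
oracle_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- oracle_mw_u(x, y)
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, function(ix) {
    oracle_mw_u(pooled[ix], pooled[-ix])
  })
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = p)
}

# BH oracle: literal double loop over the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      best <- min(best, m * p[ord[j]] / j)
    }
    q[ord[i]] <- min(1, best)
  }
  q
}

# AUC oracle: explicit loop over all positive-negative pairs.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Fisher oracle: point-probability summation with hand-written
# factorial-ratio hypergeometric probabilities (log-scale factorials).
oracle_fisher <- function(a, b, c_, d) {
  lfact <- function(k) lgamma(k + 1)
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  n <- m1 + m2
  pt_prob <- function(x) {
    exp(lfact(m1) - lfact(x) - lfact(m1 - x) +
          lfact(m2) - lfact(k - x) - lfact(m2 - (k - x)) -
          (lfact(n) - lfact(k) - lfact(n - k)))
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- vapply(support, pt_prob, numeric(1))
  p_obs <- pt_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All distinct tie-free rank configurations (which pooled ranks belong to
# x) for given group sizes.
all_rank_configs <- function(n1, n2) {
  utils::combn(n1 + n2, n1, simplify = FALSE)
}
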