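# Two-sample Mann-Whitney U and Spearman correlation, written out from
# first principles. The exact Mann-Whitney p enumerates every labeling of
# the pooled sample; the asymptotic branch uses the tie-corrected normal
# approximation with continuity correction. Spearman's exact tie-free
# null distribution for n <= 10 is obtained by a Ryser-permanent
# enumeration of the distribution of the rank-difference sum of squares.

# U statistic from midranks: U = #{x_i > y_j} + 0.5 * #{ties}
u_from_ranks <- function(ranks, idx_x, n1) {
  sum(ranks[idx_x]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. `U` counts pairs with `x > y` plus half
#' the tied pairs. The exact p-value enumerates all `choose(n1 + n2, n1)`
#' labelings of the pooled sample and sums the null probability of
#' `|U - n1 n2 / 2|` at least as large as observed; the asymptotic
#' p-value uses the normal approximation with tie-corrected variance and
#' a 0.5 continuity correction. `method = "auto"` picks the exact branch
#' when `n1 + n2 <= 16`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param method `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return Tibble with columns `statistic` (U), `p.value`, `method`.
#' @export
#' @examples
#' mw_test(c(1, 2), c(3, 4))
mw_test <- function(x, y, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (length(x) < 1 || length(y) < 1) {
    abort_domain("both samples must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) abort_domain("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u <- u_from_ranks(ranks, seq_len(n1), n1)
  if (method == "auto") {
    method <- if (n <= 16) "exact" else "asymptotic"
  }
  if (method == "exact") {
    sets <- combn(n, n1)
    mu <- n1 * n2 / 2
    d_obs <- abs(u - mu)
    d_all <- abs(apply(sets, 2, function(ix) u_from_ranks(ranks, ix, n1)) - mu)
    p <- mean(d_all >= d_obs - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(zstat, 0)))
    }
  }
  tibble(statistic = u, p.value = p, method = method)
}

# ---- Spearman ----------------------------------------------------------

# Exact tie-free null distribution of S = sum (r_i - s_i)^2 for sample
# size n, via Ryser's permanent formula applied to the matrix of
# monomials x^{(i-j)^2}: counts[S + 1] = number of permutations with that
# rank-difference sum of squares. Cached per n (n <= 10).
spearman_null_env <- new.env(parent = emptyenv())

spearman_exact_counts <- function(n) {
  key <- as.character(n)
  if (!is.null(spearman_null_env[[key]])) return(spearman_null_env[[key]])
  max_s <- n * (n^2 - 1) / 3
  len <- max_s + 1
  total <- numeric(len)
  subsets <- seq_len(2^n - 1)
  for (s in subsets) {
    js <- which(bitwAnd(s, 2^(0:(n - 1))) > 0)
    prod_poly <- 1
    for (i in seq_len(n)) {
      row_poly <- numeric(len)
      degs <- (i - js)^2
      for (d in degs) row_poly[d + 1] <- row_poly[d + 1] + 1
      nz <- which(row_poly != 0)
      new_poly <- numeric(len)
      if (length(prod_poly) == 1) {
        new_poly[nz] <- row_poly[nz]
      } else {
        pz <- which(prod_poly != 0)
        for (k in nz) {
          reach <- pz[pz + k - 1 <= len]
          new_poly[reach + k - 1] <- new_poly[reach + k - 1] +
            prod_poly[reach] * row_poly[k]
        }
      }
      prod_poly <- new_poly
    }
    sign <- (-1)^(n - length(js))
    total <- total + sign * prod_poly
  }
  total <- round(total)
  spearman_null_env[[key]] <- total
  total
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks (ties handled). The
#' two-sided p-value is exact (full enumeration of the tie-free
#' permutation null) for `n <= 10` without ties, and otherwise uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @return Tibble with columns `rho`, `p.value`, `method`.
#' @export
#' @examples
#' spearman_test(1:3, c(3, 1, 2))
spearman_test <- function(x, y) {
  if (length(x) != length(y)) abort_domain("x and y must be paired")
  n <- length(x)
  if (n < 3) abort_domain("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort_domain("samples must not contain NA")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort_degenerate("correlation undefined for a constant input")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !has_ties) {
    counts <- spearman_exact_counts(n)
    s_obs <- sum((rx - ry)^2)
    max_s <- n * (n^2 - 1) / 3
    dev <- abs(s_obs - max_s / 2)
    svals <- 0:max_s
    p <- sum(counts[abs(svals - max_s / 2) >= dev - 1e-9]) / factorial(n)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  tibble(rho = rho, p.value = min(1, p), method = method)
}
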