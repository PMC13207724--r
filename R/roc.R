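# ROC analysis: threshold sweep, AUC by pairwise concordance (the
# Mann-Whitney identity), stratified percentile-bootstrap confidence
# intervals, Youden's optimal cutoff, and combined logistic risk scores.
# Higher scores are treated as more case-like; no automatic direction
# flip is applied (AUC < 0.5 is reported as computed, with a warning).

#' ROC curve and AUC
#'
#' Builds the ROC sweep over thresholds `t` (classify positive when
#' `score >= t`) and computes the AUC both as the trapezoidal area and as
#' the pairwise concordance `(#\{pos > neg\} + 0.5 #\{ties\}) / (n1 n0)`;
#' the two are computed over exact half-integer counts and agree exactly.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1), both classes present.
#' @return Object of class `hasi_roc`: a tibble of sweep points
#'   (`threshold`, `sensitivity`, `specificity`) with attributes `auc`,
#'   `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels)) abort_domain("NA in scores or labels")
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2) {
    abort_domain("labels must be 0/1 with both classes present")
  }
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  thr <- c(sort(unique(scores)), Inf)
  # counts at each threshold: tp = #pos with score >= t, fp likewise
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  ord <- order(fp, tp)  # ascending FPR for the trapezoid
  fp_s <- fp[ord]; tp_s <- tp[ord]
  trap_num <- sum(diff(fp_s) * (head(tp_s, -1) + tail(tp_s, -1)) / 2)
  r <- rank(scores)
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2  # concordant pairs + half ties
  auc_pairs <- u / (n1 * n0)
  auc_trap <- trap_num / (n1 * n0)
  if (auc_trap != auc_pairs) {
    abort("internal error: trapezoidal and pairwise AUC disagree")
  }
  if (auc_pairs < 0.5) {
    warn("AUC below 0.5: check the score orientation (higher = more case-like)")
  }
  out <- tibble(threshold = thr,
                sensitivity = tp / n1,
                specificity = 1 - fp / n0)
  attr(out, "auc") <- auc_pairs
  attr(out, "n_pos") <- n1
  attr(out, "n_neg") <- n0
  class(out) <- c("hasi_roc", class(out))
  out
}

#' AUC of a ROC object or of raw scores
#'
#' @param x A `hasi_roc` object, or a numeric score vector.
#' @param labels Labels, required when `x` is a score vector.
#' @return The AUC.
#' @export
roc_auc <- function(x, labels = NULL) {
  if (inherits(x, "hasi_roc")) return(attr(x, "auc"))
  attr(roc_curve(x, labels), "auc")
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Nonparametric percentile interval: resamples subjects with replacement
#' *within* each class (so every replicate keeps both classes), recomputes
#' the AUC, and takes the 2.5/97.5 percent quantiles. Deterministic given
#' `seed`.
#'
#' @inheritParams roc_curve
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Seed for the resampling stream.
#' @param level Confidence level.
#' @return Tibble `auc`, `ci_low`, `ci_high`, `B`.
#' @export
auc_ci_bootstrap <- function(scores, labels, B = 2000, seed = 1,
                             level = 0.95) {
  if (B < 100) abort_domain("need at least 100 bootstrap replicates")
  labels <- as.integer(labels)
  ipos <- which(labels == 1L); ineg <- which(labels == 0L)
  if (length(ipos) < 2 || length(ineg) < 2) {
    abort_domain("each class needs at least 2 members for the bootstrap")
  }
  r_all <- rank(scores)
  point <- (sum(r_all[labels == 1L]) -
              length(ipos) * (length(ipos) + 1) / 2) /
    (length(ipos) * length(ineg))
  set.seed(stream_seed(seed, "auc-bootstrap"))
  stats <- numeric(B)
  n1 <- length(ipos); n0 <- length(ineg)
  for (b in seq_len(B)) {
    sp <- scores[ipos[sample.int(n1, n1, replace = TRUE)]]
    sn <- scores[ineg[sample.int(n0, n0, replace = TRUE)]]
    r <- rank(c(sp, sn))
    stats[b] <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  alpha <- (1 - level) / 2
  ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE)
  tibble(auc = point, ci_low = ci[1], ci_high = ci[2], B = B)
}

#' Youden's optimal cutoff
#'
#' Maximizes `J = sensitivity + specificity - 1` over the observed score
#' thresholds; ties are broken toward the lowest (most sensitive)
#' threshold.
#'
#' @param roc A `hasi_roc` object.
#' @return Tibble `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  pts <- as_tibble(roc)
  pts <- pts[is.finite(pts$threshold), ]
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(pts$threshold[best])]
  tibble(threshold = pts$threshold[pick],
         sensitivity = pts$sensitivity[pick],
         specificity = pts$specificity[pick],
         youden_j = j[pick])
}

#' Combined logistic risk scores
#'
#' In-sample fitted probabilities from a logistic model of group on the
#' listed predictors (the composite index and/or clinical covariates).
#' Feeding these scores to [roc_curve()] gives the combined-model
#' (apparent) ROC.
#'
#' @param cohort A validated cohort tibble.
#' @param index Per-subject index tibble, or `NULL` if the index is not
#'   among the predictors.
#' @param covariates Clinical covariate names to include.
#' @return Tibble `subject_id`, `score`, with the fit in `attr(, "fit")`.
#' @export
combined_scores <- function(cohort, index = NULL,
                            covariates = character(0)) {
  x <- model_design(cohort, index = index, covariates = covariates)
  if (is.null(x)) abort_domain("no predictors supplied")
  fit <- logistic_fit(x, cohort$group)
  out <- tibble(subject_id = cohort$subject_id, score = fit$fitted)
  attr(out, "fit") <- fit
  out
}
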