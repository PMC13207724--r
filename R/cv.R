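# Repeated stratified k-fold cross-validation of the index-based
# logistic model. Standardization mode matters here: "whole-cohort"
# derives z-scores from all subjects before splitting (the derivation's
# stated behaviour, which leaks test information into the standardization
# constants), while "train-fold-only" re-derives the constants from the
# training subjects of each fold.

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < k) {
      abort_domain(sprintf("class %s has fewer members (%d) than folds (%d)",
                           g, length(idx), k))
    }
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation of the index model
#'
#' Per repetition: stratified partition into `k` folds; per fold, fit the
#' logistic model (index plus optional covariates) on the other `k - 1`
#' folds and score the held-out fold; the repetition AUC is computed on
#' the pooled out-of-fold scores. Mean and SD are taken across
#' repetitions. Deterministic given `seed`.
#'
#' @param cohort A validated cohort tibble.
#' @param spec Index specification (default HASI-40), or `NULL` to use no
#'   index term.
#' @param covariates Clinical covariate names added to the model.
#' @param k Number of folds (>= 2).
#' @param repetitions Number of repeated partitions.
#' @param seed Master seed.
#' @param mode `"whole-cohort"` (z-scores from all subjects; the
#'   derivation's stated procedure) or `"train-fold-only"` (constants
#'   re-derived per fold from training subjects only).
#' @return Object of class `hasi_cv`: list with `k`, `repetitions`,
#'   `mode`, `per_repetition_auc`, `mean_auc`, `sd_auc`, and `fold_info`
#'   (per-repetition list of standardization-reference and test subject
#'   ids, for leakage auditing).
#' @export
repeated_cv_auc <- function(cohort, spec = hasi40_spec(),
                            covariates = character(0), k = 5,
                            repetitions = 100, seed = 1,
                            mode = c("whole-cohort", "train-fold-only")) {
  mode <- match.arg(mode)
  if (k < 2) abort_domain("k must be at least 2")
  if (repetitions < 1) abort_domain("repetitions must be at least 1")
  require_two_groups(cohort)
  y <- cohort$group
  n <- nrow(cohort)
  whole_index <- if (!is.null(spec)) cohort_index(cohort, spec)
  aucs <- numeric(repetitions)
  fold_info <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(stream_seed(seed, paste0("cv/", r)))
    folds <- stratified_folds(y, k)
    oof <- numeric(n)
    info_r <- vector("list", k)
    for (f in seq_len(k)) {
      test <- folds == f
      train <- !test
      if (!is.null(spec)) {
        if (mode == "whole-cohort") {
          idx <- whole_index
          ref_ids <- cohort$subject_id
        } else {
          zs <- standardize_cohort(cohort, metabolites = spec$metabolite,
                                   reference_ids = cohort$subject_id[train])
          idx <- compute_index(zs, spec)
          ref_ids <- attr(zs, "reference_ids")
        }
      } else {
        idx <- NULL
        ref_ids <- cohort$subject_id[train]
      }
      xd <- model_design(cohort, index = idx, covariates = covariates)
      fit <- suppressWarnings(
        logistic_fit(xd[train, , drop = FALSE], y[train])
      )
      xm <- cbind(1, xd[test, , drop = FALSE])
      oof[test] <- plogis(drop(xm %*% fit$coefficients))
      info_r[[f]] <- list(reference_ids = ref_ids,
                          test_ids = cohort$subject_id[test])
    }
    aucs[r] <- suppressWarnings(roc_auc(oof, y))
    fold_info[[r]] <- info_r
  }
  structure(
    list(k = k, repetitions = repetitions, mode = mode,
         per_repetition_auc = aucs,
         mean_auc = mean(aucs), sd_auc = sd(aucs),
         fold_info = fold_info),
    class = "hasi_cv"
  )
}

#' @export
print.hasi_cv <- function(x, ...) {
  cat(sprintf("Repeated stratified %d-fold CV (%d repetitions, %s standardization)\n",
              x$k, x$repetitions, x$mode))
  cat(sprintf("mean out-of-fold AUC %.3f (SD %.3f)\n", x$mean_auc, x$sd_auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hasi_cv <- function(x, ...) {
  tibble(repetition = seq_len(x$repetitions), auc = x$per_repetition_auc)
}

#' @exportS3Method generics::glance
glance.hasi_cv <- function(x, ...) {
  tibble(k = x$k, repetitions = x$repetitions, mode = x$mode,
         mean_auc = x$mean_auc, sd_auc = x$sd_auc)
}
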