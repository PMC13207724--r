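# End-to-end analysis pipeline: load or simulate a cohort, standardize,
# compute the composite index, run the panel comparison with FDR control,
# LVEF correlations, uni- and multivariable logistic models, ROC analyses
# (index, age, combined) and repeated cross-validation, and collect
# everything into one report object that serializes deterministically.

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)),
          class = "hasindex_pipeline_error", stage = stage, parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load/simulate and validate the cohort; whole-cohort
#' standardization and HASI-40 computation; per-metabolite panel
#' comparison with BH FDR; Spearman correlations with LVEF; index group
#' summary; univariable and multivariable logistic models; ROC analyses
#' for the index, age, and the combined index + age model (with
#' stratified bootstrap CIs and Youden cutoffs); and repeated stratified
#' k-fold cross-validation. Fully deterministic given `seed`.
#'
#' @param cohort A validated cohort tibble, a path to a cohort CSV, or
#'   `NULL` to simulate from `synthetic_config`.
#' @param synthetic_config Generator configuration used when `cohort` is
#'   `NULL` (default [default_synthetic_config()]).
#' @param spec Index specification (default HASI-40).
#' @param covariates Covariates of the multivariable model.
#' @param k,repetitions Cross-validation folds and repetitions.
#' @param B Bootstrap replicates for AUC confidence intervals.
#' @param cv_mode Standardization mode inside cross-validation.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `hasi_report` with sections `cohort_summary`,
#'   `panel_comparison`, `correlations`, `index_summary`, `models`,
#'   `roc`, `cv`, `provenance`.
#' @export
#' @examples
#' rep <- run_pipeline(seed = 7, repetitions = 5, B = 200)
#' rep$index_summary
run_pipeline <- function(cohort = NULL,
                         synthetic_config = default_synthetic_config(),
                         spec = hasi40_spec(),
                         covariates = c("age", "sex", "bmi", "diabetes",
                                        "dyslipidemia"),
                         k = 5, repetitions = 100, B = 2000,
                         cv_mode = "whole-cohort", seed = 1) {
  cohort <- pipeline_stage("load", {
    if (is.null(cohort)) {
      simulate_cohort(synthetic_config, seed = seed)
    } else if (is.character(cohort)) {
      read_cohort(cohort)
    } else {
      validate_cohort(cohort)
    }
  })
  pipeline_stage("load", require_two_groups(cohort))

  z <- pipeline_stage("standardize", standardize_cohort(cohort))
  index <- pipeline_stage("index", compute_index(z, spec))
  panel_cmp <- pipeline_stage("panel-comparison",
                              compare_panel(cohort, index = index))
  correlations <- pipeline_stage("correlations",
                                 correlate_with_lvef(cohort, index = index))
  index_summary <- pipeline_stage("index-summary",
                                  index_group_summary(index, cohort))
  uni <- pipeline_stage("univariable-model",
                        suppressWarnings(fit_univariable_index(cohort, index)))
  multi <- pipeline_stage("multivariable-model",
                          suppressWarnings(
                            fit_multivariable_index(cohort, index,
                                                    covariates = covariates)))
  roc <- pipeline_stage("roc", {
    df <- left_join(cohort[c("subject_id", "group", "age")], index,
                    by = "subject_id")
    one_roc <- function(scores, label) {
      rc <- suppressWarnings(roc_curve(scores, df$group))
      ci <- auc_ci_bootstrap(scores, df$group, B = B,
                             seed = stream_seed(seed, paste0("roc/", label)))
      yj <- youden_cutoff(rc)
      list(curve = as_tibble(rc), auc = attr(rc, "auc"),
           ci_low = ci$ci_low, ci_high = ci$ci_high, youden = yj)
    }
    comb <- combined_scores(cohort, index = index, covariates = "age")
    list(index = one_roc(df$index, "index"),
         age = one_roc(df$age, "age"),
         combined = one_roc(comb$score, "combined"))
  })
  cv <- pipeline_stage("cv", repeated_cv_auc(
    cohort, spec = spec, k = k, repetitions = repetitions,
    seed = stream_seed(seed, "cv"), mode = cv_mode
  ))
  cv$fold_info <- NULL  # audit detail, not part of the serialized report

  cohort_summary <- pipeline_stage("summary", {
    cohort |>
      group_by(.data$group) |>
      summarise(
        n = dplyr::n(),
        age_median = median(.data$age),
        bmi_median = median(.data$bmi),
        male = sum(.data$sex == "male"),
        diabetes = sum(.data$diabetes),
        dyslipidemia = sum(.data$dyslipidemia),
        lvef_median = median(.data$lvef),
        .groups = "drop"
      )
  })

  structure(
    list(
      cohort_summary = cohort_summary,
      panel_comparison = panel_cmp,
      correlations = correlations,
      index_summary = index_summary,
      models = list(
        # a non-converged fit (separation is a real risk at n = 42 with
        # six predictors) keeps its section, marked by converged = FALSE
        # with the raw coefficients and warnings in place of odds ratios
        univariable = list(converged = uni$fit$converged,
                           tidy = tidy(uni$fit), or = uni$or,
                           warnings = uni$fit$warnings),
        multivariable = list(converged = multi$fit$converged,
                             tidy = tidy(multi$fit), or = multi$or,
                             warnings = multi$fit$warnings)
      ),
      roc = roc,
      cv = list(k = cv$k, repetitions = cv$repetitions, mode = cv$mode,
                per_repetition_auc = cv$per_repetition_auc,
                mean_auc = cv$mean_auc, sd_auc = cv$sd_auc),
      provenance = list(
        seed = seed,
        package_version = as.character(utils::packageVersion("hasindex")),
        index = attr(spec, "index_name") %||% "index",
        config_hash = rlang::hash(list(spec = as_tibble(spec),
                                       covariates = covariates,
                                       k = k, repetitions = repetitions,
                                       B = B, cv_mode = cv_mode))
      )
    ),
    class = "hasi_report"
  )
}

#' Serialize a report to JSON
#'
#' Deterministic serialization: the same report object always yields the
#' same JSON string (no timestamps are embedded).
#'
#' @param report A `hasi_report`.
#' @param path Optional output path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.hasi_report <- function(x, ...) {
  cat("HASI analysis report\n")
  cat("  groups: n =", paste(x$cohort_summary$n, collapse = " / "), "\n")
  cat(sprintf("  index medians (group 0 / 1): %.3f / %.3f\n",
              x$index_summary$median[x$index_summary$group == 0],
              x$index_summary$median[x$index_summary$group == 1]))
  show_or <- function(label, sec) {
    if (is.null(sec$or)) {
      cat("  ", label, ": fit did not converge (separation suspected)\n",
          sep = "")
    } else {
      or <- sec$or
      cat(sprintf("  %s OR per unit: %.2f (%.2f-%.2f)\n", label,
                  or$odds_ratio[or$term == "hasi40"],
                  or$ci_low[or$term == "hasi40"],
                  or$ci_high[or$term == "hasi40"]))
    }
  }
  show_or("univariable", x$models$univariable)
  show_or("adjusted", x$models$multivariable)
  cat(sprintf("  AUC index %.3f, age %.3f, combined %.3f; CV mean AUC %.3f\n",
              x$roc$index$auc, x$roc$age$auc, x$roc$combined$auc,
              x$cv$mean_auc))
  invisible(x)
}
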