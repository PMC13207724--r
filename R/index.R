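# Cohort-wide z-standardization and the signed composite index. The
# index is the plain signed sum of per-metabolite z-scores; it is not
# re-standardized after summation.

#' Standardize metabolite concentrations to z-scores
#'
#' Computes per-metabolite z-scores `(value - mean) / sd`, with mean and
#' sample SD (n - 1 denominator) taken over the *reference* subjects: all
#' subjects by default ("whole-cohort" standardization, the derivation's
#' stated behaviour), or a subset (for example the training subjects of a
#' cross-validation fold, avoiding test-set leakage).
#'
#' @param cohort A validated cohort tibble.
#' @param metabolites Metabolite columns to standardize (default: the full
#'   panel intersected with the cohort's columns).
#' @param reference_ids Subject ids over which the mean and SD are
#'   computed; `NULL` means all subjects.
#' @return A tibble of class `hasi_zscores`: `subject_id` plus one z-score
#'   column per metabolite, with the standardization constants in
#'   `attr(, "constants")` (tibble `metabolite`, `mean`, `sd`).
#' @export
#' @examples
#' cohort <- simulate_cohort(default_synthetic_config(), seed = 1)
#' z <- standardize_cohort(cohort)
#' colMeans(as.matrix(z[hasi40_spec()$metabolite]))
standardize_cohort <- function(cohort, metabolites = NULL,
                               reference_ids = NULL) {
  if (is.null(metabolites)) {
    metabolites <- intersect(PANEL_METABOLITES, names(cohort))
  }
  missing <- setdiff(metabolites, names(cohort))
  if (length(missing) > 0) {
    abort_schema(paste0("metabolite column(s) absent from cohort: ",
                        paste(missing, collapse = ", ")))
  }
  ref <- if (is.null(reference_ids)) rep(TRUE, nrow(cohort)) else
    cohort$subject_id %in% reference_ids
  if (sum(ref) < 2) {
    abort_domain("need at least 2 reference subjects for standardization")
  }
  x <- as.matrix(cohort[metabolites])
  mu <- colMeans(x[ref, , drop = FALSE])
  sdev <- apply(x[ref, , drop = FALSE], 2, sd)
  if (any(sdev <= 0)) {
    abort_degenerate(paste0(
      "zero standard deviation (constant column) for: ",
      paste(metabolites[sdev <= 0], collapse = ", ")
    ))
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  out <- dplyr::bind_cols(tibble(subject_id = cohort$subject_id),
                          as_tibble(z))
  attr(out, "constants") <- tibble(metabolite = metabolites,
                                   mean = unname(mu), sd = unname(sdev))
  attr(out, "reference_ids") <- cohort$subject_id[ref]
  class(out) <- c("hasi_zscores", class(out))
  out
}

#' Standardization constants of a z-score table
#'
#' @param z A `hasi_zscores` tibble.
#' @return Tibble with columns `metabolite`, `mean`, `sd`.
#' @export
zscore_constants <- function(z) attr(z, "constants")

#' @exportS3Method generics::tidy
tidy.hasi_zscores <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"subject_id",
                      names_to = "metabolite", values_to = "z")
}

#' Compute a signed composite index from z-scores
#'
#' Evaluates `sum(sign * z(metabolite))` per subject for the terms of an
#' index specification. With [hasi40_spec()] this is
#' `z(3-methylhistidine) - z(sarcosine) - z(taurine) - z(serine)`.
#'
#' @param z A `hasi_zscores` tibble (see [standardize_cohort()]).
#' @param spec An [index_spec()]; defaults to HASI-40.
#' @return Tibble with columns `subject_id` and `index`; the spec is kept
#'   in `attr(, "spec")`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_synthetic_config(), seed = 1)
#' idx <- compute_index(standardize_cohort(cohort))
#' head(idx)
compute_index <- function(z, spec = hasi40_spec()) {
  missing <- setdiff(spec$metabolite, names(z))
  if (length(missing) > 0) {
    abort_schema(paste0("index metabolite(s) absent from z-scores: ",
                        paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(as_tibble(z)[spec$metabolite]) %*% spec$sign
  if (any(!is.finite(vals))) {
    abort_validation("non-finite index value(s)")
  }
  out <- tibble(subject_id = z$subject_id, index = as.numeric(vals))
  attr(out, "spec") <- spec
  out
}

#' Per-subject index values for a cohort
#'
#' Convenience wrapper: whole-cohort standardization of the spec's
#' metabolites followed by [compute_index()].
#'
#' @inheritParams standardize_cohort
#' @inheritParams compute_index
#' @return Tibble `subject_id`, `index`.
#' @export
cohort_index <- function(cohort, spec = hasi40_spec(),
                         reference_ids = NULL) {
  z <- standardize_cohort(cohort, metabolites = spec$metabolite,
                          reference_ids = reference_ids)
  compute_index(z, spec)
}

#' Per-group summary of index values
#'
#' Median and quartiles (linear-interpolation convention) of the index per
#' group.
#'
#' @param index Tibble `subject_id`, `index` (see [compute_index()]).
#' @param cohort The cohort supplying group labels.
#' @return Tibble `group`, `n`, `q1`, `median`, `q3`.
#' @export
index_group_summary <- function(index, cohort) {
  df <- dplyr::left_join(index, cohort[c("subject_id", "group")],
                         by = "subject_id")
  require_two_groups(df)
  df |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      q1 = quartiles(.data$index)[1],
      median = quartiles(.data$index)[2],
      q3 = quartiles(.data$index)[3],
      .groups = "drop"
    )
}
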