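# Cohort tables: one row per subject with group label (0 = LVEF 40-49%,
# 1 = LVEF < 40%), LVEF, clinical covariates and the 23 metabolite
# concentrations in umol/L. Validation is reject-by-default: no value is
# imputed, any malformed row fails the whole table unless the caller asks
# for row-wise deletion explicitly.

COHORT_BASE_COLUMNS <- c("subject_id", "group", "lvef", "age", "sex",
                         "bmi", "diabetes", "dyslipidemia")

#' Validate a cohort table
#'
#' Checks the cohort schema and content invariants: unique subject ids,
#' group labels in \{0, 1\}, non-negative finite metabolite
#' concentrations, and no missing values (the analysis applies no
#' imputation). Rows with missing or non-finite metabolite values are
#' rejected unless `drop_incomplete = TRUE`, in which case they are
#' removed with a message stating the count.
#'
#' @param cohort A data frame in the cohort schema.
#' @param panel Panel tibble; its metabolites must all be present as
#'   columns.
#' @param drop_incomplete Drop (rather than reject) rows with missing
#'   metabolite or covariate values.
#' @return The validated cohort as a tibble.
#' @export
validate_cohort <- function(cohort, panel = aa_panel(),
                            drop_incomplete = FALSE) {
  cohort <- as_tibble(cohort)
  needed <- c(COHORT_BASE_COLUMNS, panel$metabolite)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort_schema(paste0(
      "cohort is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  mets <- panel$metabolite
  for (m in mets) {
    if (!is.numeric(cohort[[m]])) {
      abort_validation(paste0("metabolite column is not numeric: ", m))
    }
  }
  check_cols <- c("group", "age", "bmi", mets)
  incomplete <- rowSums(is.na(cohort[check_cols])) > 0 |
    !apply(as.matrix(cohort[mets]), 1, function(r) all(is.finite(r)))
  if (any(incomplete)) {
    if (!drop_incomplete) {
      abort_validation(paste0(
        sum(incomplete), " row(s) contain missing or non-finite values; ",
        "no imputation is applied (use drop_incomplete = TRUE to delete)"
      ))
    }
    message("dropping ", sum(incomplete), " incomplete row(s)")
    cohort <- cohort[!incomplete, , drop = FALSE]
  }
  if (anyDuplicated(cohort$subject_id)) {
    abort_validation("duplicate subject_id values")
  }
  if (!all(cohort$group %in% c(0, 1))) {
    abort_validation("group labels must be 0 (LVEF 40-49%) or 1 (LVEF < 40%)")
  }
  conc <- as.matrix(cohort[mets])
  if (any(conc < 0)) {
    abort_validation("negative metabolite concentration(s)")
  }
  cohort$group <- as.integer(cohort$group)
  cohort
}

# both-groups-present guard used by every group comparison
require_two_groups <- function(cohort) {
  if (!all(c(0L, 1L) %in% cohort$group)) {
    abort_validation("both groups (0 and 1) must be non-empty")
  }
  invisible(cohort)
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first cohort file and validates
#' it against the panel. Metabolite column names are canonicalized (see
#' [canonical_metabolite()]).
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_cohort
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, panel = aa_panel(), drop_incomplete = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("cohort file does not exist: ", path),
          class = "hasindex_io_error")
  }
  # base read.csv parses doubles via strtod, which is exact to the ulp
  # (required for the lossless round-trip contract)
  raw <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (nrow(raw) > 0 && is.logical(raw$sex)) raw$sex <- as.character(raw$sex)
  for (col in c("diabetes", "dyslipidemia")) {
    if (col %in% names(raw) && !is.logical(raw[[col]])) {
      raw[[col]] <- as.logical(raw[[col]])
    }
  }
  base_idx <- names(raw) %in% COHORT_BASE_COLUMNS
  names(raw)[!base_idx] <- canonical_metabolite(names(raw)[!base_idx])
  validate_cohort(raw, panel = panel, drop_incomplete = drop_incomplete)
}

#' Write a cohort table to CSV
#'
#' Serializes numbers at full precision so that
#' `read_cohort(write_cohort(cohort))` reproduces the cohort exactly.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits round-trip any IEEE double exactly
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
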