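# Panel-level comparisons: per-metabolite two-group tests with FDR
# control, and rank correlations of metabolites (plus the composite
# index) with LVEF.

#' Per-metabolite two-group comparison with FDR control
#'
#' Runs one Mann-Whitney test per unique panel metabolite between group 0
#' and group 1, reports per-group medians and quartiles, and
#' Benjamini-Hochberg-adjusts the raw p-values over the family of unique
#' metabolites. The composite index, if supplied, is tested separately
#' and is *not* part of the metabolite FDR family; its row carries
#' `q.value = NA`.
#'
#' @param cohort A validated cohort tibble.
#' @param panel Panel tibble (defines the family and the output order).
#' @param index Optional per-subject index tibble (`subject_id`, `index`)
#'   appended as a final row labelled by the index name.
#' @param method Mann-Whitney method passed to [mw_test()].
#' @return Tibble with columns `variable`, `group0_median`, `group0_q1`,
#'   `group0_q3`, `group1_median`, `group1_q1`, `group1_q3`, `statistic`,
#'   `p.value`, `q.value`, `method`.
#' @export
compare_panel <- function(cohort, panel = aa_panel(), index = NULL,
                          method = "auto") {
  require_two_groups(cohort)
  g0 <- cohort$group == 0L
  one_row <- function(name, values) {
    x0 <- values[g0]; x1 <- values[!g0]
    tst <- mw_test(x0, x1, method = method)
    q0 <- quartiles(x0); q1 <- quartiles(x1)
    tibble(
      variable = name,
      group0_median = q0[2], group0_q1 = q0[1], group0_q3 = q0[3],
      group1_median = q1[2], group1_q1 = q1[1], group1_q3 = q1[3],
      statistic = tst$statistic, p.value = tst$p.value, method = tst$method
    )
  }
  res <- bind_rows(lapply(panel$metabolite,
                          function(m) one_row(m, cohort[[m]])))
  res$q.value <- adjust_bh(res$p.value)
  if (!is.null(index)) {
    df <- left_join(index, cohort[c("subject_id", "group")],
                    by = "subject_id")
    name <- attr(index, "spec") |> attr("index_name") %||% "index"
    x0 <- df$index[df$group == 0L]; x1 <- df$index[df$group == 1L]
    tst <- mw_test(x0, x1, method = method)
    qq0 <- quartiles(x0); qq1 <- quartiles(x1)
    irow <- tibble(
      variable = name,
      group0_median = qq0[2], group0_q1 = qq0[1], group0_q3 = qq0[3],
      group1_median = qq1[2], group1_q1 = qq1[1], group1_q3 = qq1[3],
      statistic = tst$statistic, p.value = tst$p.value, method = tst$method,
      q.value = NA_real_
    )
    res <- bind_rows(res, irow)
  }
  res[c("variable", "group0_median", "group0_q1", "group0_q3",
        "group1_median", "group1_q1", "group1_q3", "statistic",
        "p.value", "q.value", "method")]
}

#' Spearman correlations of metabolites (and index) with LVEF
#'
#' @param cohort A validated cohort tibble with an `lvef` column.
#' @param panel Panel tibble.
#' @param index Optional per-subject index tibble; appended as a final
#'   row.
#' @return Tibble with columns `variable`, `rho`, `p.value`, `method`.
#' @export
correlate_with_lvef <- function(cohort, panel = aa_panel(), index = NULL) {
  if (anyNA(cohort$lvef)) {
    abort_validation("lvef contains missing values")
  }
  rows <- lapply(panel$metabolite, function(m) {
    r <- spearman_test(cohort[[m]], cohort$lvef)
    tibble(variable = m, rho = r$rho, p.value = r$p.value,
           method = r$method)
  })
  res <- bind_rows(rows)
  if (!is.null(index)) {
    df <- left_join(cohort["subject_id"], index, by = "subject_id")
    name <- attr(index, "spec") |> attr("index_name") %||% "index"
    r <- spearman_test(df$index, cohort$lvef)
    res <- bind_rows(res, tibble(variable = name, rho = r$rho,
                                 p.value = r$p.value, method = r$method))
  }
  res
}
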