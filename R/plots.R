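# Presentation-layer figures: group-wise index distribution, LVEF
# correlation profile, and overlaid ROC curves. Purely presentational --
# every number shown is computed elsewhere.

#' Strip/box plot of index values by group
#'
#' @param index Per-subject index tibble (`subject_id`, `index`).
#' @param cohort Cohort supplying group labels.
#' @return A ggplot object.
#' @export
plot_index_groups <- function(index, cohort) {
  df <- left_join(index, cohort[c("subject_id", "group")],
                  by = "subject_id")
  df$group <- factor(df$group, levels = c(0, 1),
                     labels = c("LVEF 40-49%", "LVEF < 40%"))
  ggplot(df, aes(x = .data$group, y = .data$index)) +
    geom_boxplot(outlier.shape = NA, width = 0.45, fill = "grey92") +
    geom_jitter(width = 0.12, height = 0, size = 1.6, alpha = 0.8) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = NULL, y = "HASI-40 index (signed z-score sum)") +
    theme_minimal()
}

#' Correlation profile of metabolites (and index) with LVEF
#'
#' @param correlations Tibble from [correlate_with_lvef()].
#' @return A ggplot object (horizontal bar chart of Spearman rho).
#' @export
plot_lvef_correlations <- function(correlations) {
  df <- correlations
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot(df, aes(x = .data$rho, y = .data$variable,
                 fill = .data$p.value < 0.05)) +
    geom_col() +
    scale_fill_manual(values = c(`TRUE` = "#2166AC", `FALSE` = "grey70"),
                      name = "p < 0.05") +
    labs(x = "Spearman rho with LVEF", y = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hasi_roc <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                colour = "grey60") +
    geom_path() +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    theme_minimal()
}

#' Overlaid ROC curves from a report
#'
#' @param report A `hasi_report`.
#' @return A ggplot object overlaying the index, age, and combined ROC
#'   curves.
#' @export
plot_report_rocs <- function(report) {
  grab <- function(name) {
    dplyr::mutate(report$roc[[name]]$curve,
                  model = sprintf("%s (AUC %.3f)", name,
                                  report$roc[[name]]$auc))
  }
  df <- bind_rows(grab("index"), grab("age"), grab("combined"))
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity,
                 colour = .data$model)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                colour = "grey60") +
    geom_path() +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    theme_minimal() +
    theme(legend.position = "bottom")
}

#' Write report figures to a directory
#'
#' Emits three vector (PDF) figures: the group-wise index plot, the LVEF
#' correlation profile, and the overlaid ROC curves. No new numbers are
#' computed.
#'
#' @param report A `hasi_report`.
#' @param cohort The cohort the report was computed from.
#' @param index The per-subject index values.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the written file paths.
#' @export
make_figures <- function(report, cohort, index, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", out_dir),
                   class = "hasindex_io_error")
  }
  paths <- file.path(out_dir, c("index_by_group.pdf",
                                "lvef_correlations.pdf",
                                "roc_curves.pdf"))
  plots <- list(plot_index_groups(index, cohort),
                plot_lvef_correlations(report$correlations),
                plot_report_rocs(report))
  for (i in seq_along(paths)) {
    ggsave(paths[i], plots[[i]], width = 6, height = 5, device = "pdf")
  }
  paths
}
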