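# ggplot2 views of the main result types.

#' Forest plot of enrichment odds ratios
#'
#' @param object One or more `dgv_enrichment` rows (bind rows of
#'   [pdgv_enrichment()] results for several comparisons).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dgv_enrichment
#' @export
autoplot.dgv_enrichment <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(comparison = paste0(
      .data$cancer, " vs ", .data$control,
      ifelse(is.na(.data$ethnicity), "", paste0(" (", .data$ethnicity, ")"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = .data$comparison)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (pDGV : rare synonymous alleles)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Corrected-VAF density plot: TSG pDGVs vs non-TSG controls
#'
#' @param tsg_vafs,control_vafs Numeric corrected tumor VAFs.
#' @return A ggplot.
#' @export
plot_vaf_densities <- function(tsg_vafs, control_vafs) {
  df <- bind_rows(
    tibble(vaf = tsg_vafs, group = "pDGV (TSG)"),
    tibble(vaf = control_vafs, group = "truncating non-TSG control"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vaf, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, adjust = 0.8) +
    ggplot2::labs(x = "purity-corrected tumor VAF", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Paired primary/metastatic corrected-VAF slope plot
#'
#' @param pairs Tibble with `primary`, `metastatic` and optionally a
#'   `label` column (one row per shared locus).
#' @return A ggplot.
#' @export
plot_paired_vaf <- function(pairs) {
  assert_cols(pairs, c("primary", "metastatic"), "pairs")
  df <- pairs %>%
    mutate(.pair = dplyr::row_number()) %>%
    tidyr::pivot_longer(c("primary", "metastatic"), names_to = "site",
                        values_to = "vaf") %>%
    mutate(site = factor(.data$site, levels = c("primary", "metastatic")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$vaf,
                                   group = .data$.pair)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "purity-corrected VAF") +
    ggplot2::theme_minimal()
}

#' Filter-cascade waterfall for a pDGV result
#'
#' Bars show how many calls each successive filter removed (first
#' failing filter attribution), ending at the retained pDGV count.
#'
#' @param x A `pdgv_result`.
#' @return A ggplot.
#' @export
plot_filter_cascade <- function(x) {
  stopifnot(inherits(x, "pdgv_result"))
  fs <- filter_summary(x) %>%
    mutate(filter = factor(.data$filter, levels = rev(.pdgv_filters)))
  ggplot2::ggplot(fs, ggplot2::aes(x = .data$removed, y = .data$filter)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "calls removed", y = NULL,
                  subtitle = sprintf("%d of %d calls retained as pDGVs",
                                     nrow(x$pdgvs), nrow(x$trace))) +
    ggplot2::theme_minimal()
}
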