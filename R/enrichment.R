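# Case-control burden enrichment: pDGV vs rare-synonymous alternative
# allele counts compared across cohorts with a two-sided Fisher test, and
# the CADD deleteriousness comparison against a per-patient sampled
# background of truncating variants in non-TSGs.

#' Count alternative alleles over a gene panel
#'
#' Heterozygous calls contribute one allele, homozygous-alternate calls
#' two. Calls outside the panel contribute nothing; calls with missing
#' genotype are skipped with a warning.
#'
#' @param variants Tibble with `gene` and `genotype` columns (pDGVs or
#'   rare synonymous variants).
#' @param panel Character vector of panel genes.
#' @return Integer allele count.
#' @export
count_alt_alleles <- function(variants, panel) {
  if (nrow(variants) == 0) return(0L)
  assert_cols(variants, c("gene", "genotype"), "variants")
  miss <- is.na(variants$genotype) | variants$genotype == "missing"
  if (any(miss)) {
    warn(sprintf("%d variant(s) with missing genotype skipped", sum(miss)))
  }
  v <- variants[!miss & variants$gene %in% panel, , drop = FALSE]
  sum(ifelse(v$genotype == "hom_alt", 2L, 1L))
}

#' Derive the enrichment gene panel
#'
#' The union of genes harboring at least one pDGV in any contributing
#' cohort; the panel over which alleles are counted in the enrichment
#' test.
#'
#' @param ... pDGV tibbles (or `pdgv_result` objects), one per cohort.
#' @return Character vector of genes.
#' @export
derive_gene_panel <- function(...) {
  sets <- purrr::map(list(...), function(x) {
    if (inherits(x, "pdgv_result")) x <- x$pdgvs
    unique(x$gene[!is.na(x$gene)])
  })
  panel <- sort(unique(unlist(sets)))
  if (length(panel) == 0) abort("no genes harbor pDGVs: empty panel")
  panel
}

#' Two-sided Fisher's exact test on a 2x2 allele-count table
#'
#' Cells: `a` = cancer pDGV alleles, `b` = cancer rare-synonymous
#' alleles, `c` = control pDGV alleles, `d` = control rare-synonymous
#' alleles. The p-value is the exact conditional two-sided p
#' (sum of hypergeometric probabilities no larger than the observed
#' table's). Two odds ratios are reported: the sample cross-product
#' `(a*d)/(b*c)` (primary; +0.5 added to every cell when any cell is
#' zero) and the conditional-MLE estimate. The 95% CI is the Wald
#' interval on the log cross-product OR.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return One-row tibble of class `dgv_enrichment` with `a`-`d`,
#'   `odds_ratio`, `or_mle`, `ci_low`, `ci_high`, `p_value`,
#'   `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  if (sum(cells) == 0) abort("all four cells are zero")
  m <- matrix(c(a, c, b, d), nrow = 2)  # rows: pDGV/syn, cols: cancer/control
  if (degenerate) {
    p <- 1
    or_mle <- NA_real_
  } else {
    ft <- stats::fisher.test(m, alternative = "two.sided")
    p <- ft$p.value
    or_mle <- unname(ft$estimate)
  }
  haldane <- any(cells == 0)
  cc <- if (haldane) cells + 0.5 else cells
  or_cross <- (cc[["a"]] * cc[["d"]]) / (cc[["b"]] * cc[["c"]])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or_cross) + c(-1, 1) * qnorm(0.975) * se)
  out <- tibble(a = a, b = b, c = c, d = d,
                odds_ratio = unname(or_cross), or_mle = or_mle,
                ci_low = ci[1], ci_high = ci[2],
                p_value = p, haldane = haldane, degenerate = degenerate)
  class(out) <- c("dgv_enrichment", class(out))
  out
}

#' pDGV burden enrichment between a cancer and a control cohort
#'
#' Builds the 2x2 alternative-allele table over a gene panel (pDGV vs
#' rare-synonymous alleles, cancer vs control) and applies the two-sided
#' Fisher test. Ethnicity matching is performed by subsetting the inputs
#' to `ethnicity` before counting when the tibbles carry that column.
#'
#' @param cancer_pdgvs,cancer_syn pDGV and rare-synonymous tibbles of the
#'   cancer cohort.
#' @param control_pdgvs,control_syn Same for the control cohort.
#' @param panel Gene panel (default: derived from the two pDGV sets).
#' @param ethnicity Optional ethnicity label to subset all four inputs
#'   (requires an `ethnicity` column).
#' @param cancer_label,control_label Cohort labels carried in the result.
#' @return A `dgv_enrichment` row with cohort labels and panel size.
#' @export
pdgv_enrichment <- function(cancer_pdgvs, cancer_syn, control_pdgvs,
                            control_syn, panel = NULL, ethnicity = NULL,
                            cancer_label = "cancer",
                            control_label = "control") {
  grab <- function(x) if (inherits(x, "pdgv_result")) x$pdgvs else x
  cancer_pdgvs <- grab(cancer_pdgvs); control_pdgvs <- grab(control_pdgvs)
  if (!is.null(ethnicity)) {
    subset_eth <- function(x) {
      assert_cols(x, "ethnicity", "cohort table (ethnicity matching)")
      filter(x, .data$ethnicity == !!ethnicity)
    }
    cancer_pdgvs <- subset_eth(cancer_pdgvs)
    cancer_syn <- subset_eth(cancer_syn)
    control_pdgvs <- subset_eth(control_pdgvs)
    control_syn <- subset_eth(control_syn)
  }
  panel <- panel %||% derive_gene_panel(cancer_pdgvs, control_pdgvs)
  res <- fisher_exact_2x2(
    count_alt_alleles(cancer_pdgvs, panel),
    count_alt_alleles(cancer_syn, panel),
    count_alt_alleles(control_pdgvs, panel),
    count_alt_alleles(control_syn, panel)
  )
  res$cancer <- cancer_label
  res$control <- control_label
  res$ethnicity <- ethnicity %||% NA_character_
  res$panel_size <- length(panel)
  res
}

#' @export
print.dgv_enrichment <- function(x, ...) {
  cat("<dgv_enrichment>\n")
  NextMethod()
  invisible(x)
}

#' Tidy an enrichment result
#' @param x A `dgv_enrichment`.
#' @param ... Unused.
#' @return A plain tibble with one row per comparison.
#' @method tidy dgv_enrichment
#' @export
tidy.dgv_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "dgv_enrichment")
  out
}

#' @rdname tidy.dgv_enrichment
#' @method glance dgv_enrichment
#' @export
glance.dgv_enrichment <- function(x, ...) {
  tidy(x) %>%
    select(any_of(c("odds_ratio", "ci_low", "ci_high", "p_value",
                    "panel_size", "cancer", "control", "ethnicity")))
}

#' Sample the CADD comparison background
#'
#' Draws up to `n_per_patient` protein-truncating variants in non-TSGs
#' from each patient (seeded, reproducible) to serve as the background
#' score distribution against which pDGV CADD scores are compared.
#'
#' @param calls Annotated cohort calls (must carry `patient_id`, `gene`,
#'   `effect`/`canonical_effect`, `cadd_phred`).
#' @param roles Gene role tibble.
#' @param n_per_patient Variants sampled per patient (default 20).
#' @param seed Integer seed controlling the resample.
#' @return Tibble of sampled background variants.
#' @export
sample_cadd_background <- function(calls, roles, n_per_patient = 20,
                                   seed = 1L) {
  eff <- effective_effect(calls$effect, calls$canonical_effect)
  pool <- calls[eff %in% .truncating_effects &
                  gene_role(calls$gene, roles) != "TSG" &
                  !is.na(calls$cadd_phred), , drop = FALSE]
  withr::with_seed(seed, {
    pool %>%
      group_by(.data$patient_id) %>%
      slice_sample(n = n_per_patient) %>%
      ungroup()
  })
}

#' Compare CADD deleteriousness of pDGVs against background variants
#'
#' Two-sided rank test on Phred-scaled CADD scores. The groups are
#' independent draws of unequal size, so the unpaired Wilcoxon rank-sum
#' test is used (exact for small tie-free samples).
#'
#' @param pdgv_scores,background_scores Numeric CADD Phred scores.
#' @return List with `p_value`, `statistic` (rank-sum W) and group
#'   medians.
#' @export
compare_cadd <- function(pdgv_scores, background_scores) {
  if (length(pdgv_scores) == 0 || length(background_scores) == 0) {
    abort("both score sets must be non-empty")
  }
  if (length(unique(c(pdgv_scores, background_scores))) == 1) {
    return(list(p_value = 1, statistic = NA_real_,
                median_pdgv = median(pdgv_scores),
                median_background = median(background_scores)))
  }
  wt <- suppressWarnings(stats::wilcox.test(pdgv_scores, background_scores,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_pdgv = median(pdgv_scores),
       median_background = median(background_scores))
}

#' Simulate enrichment allele counts under a known rate ratio
#'
#' Draws independent Poisson allele counts for a cancer and a control
#' cohort whose true pDGV-to-synonymous rate ratio is `rate_ratio`; used
#' to check confidence-interval calibration of the enrichment odds
#' ratio. Default means mirror a WCM-sized cancer cohort against a much
#' larger population control.
#'
#' @param n_rep Number of replicate tables.
#' @param rate_ratio True odds/rate ratio (cancer vs control).
#' @param cancer_pdgv_mean Expected cancer pDGV allele count at
#'   `rate_ratio = 1` is `control_ratio * cancer_syn_mean`; the cancer
#'   pDGV mean is that scaled by `rate_ratio`.
#' @param cancer_syn_mean,control_syn_mean Expected synonymous allele
#'   counts.
#' @param control_ratio Control pDGV-to-synonymous rate.
#' @param seed Integer seed.
#' @return Tibble with one row per replicate: cells `a`-`d` and the true
#'   ratio.
#' @export
simulate_enrichment_counts <- function(n_rep = 500, rate_ratio = 2,
                                       cancer_syn_mean = 300,
                                       control_syn_mean = 4100,
                                       control_ratio = 0.1,
                                       seed = 1L) {
  withr::with_seed(seed, {
    tibble(
      rep = seq_len(n_rep),
      a = rpois(n_rep, rate_ratio * control_ratio * cancer_syn_mean),
      b = rpois(n_rep, cancer_syn_mean),
      c = rpois(n_rep, control_ratio * control_syn_mean),
      d = rpois(n_rep, control_syn_mean),
      true_ratio = rate_ratio
    )
  })
}
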