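# Loss-of-heterozygosity analysis: purity-corrected tumor VAFs at
# germline loci, the ratio-threshold LOH call, background controls in
# non-TSGs, and the serial-tumor (deepening-LOH) comparisons.

#' Purity-corrected tumor VAF
#'
#' Divides the raw tumor VAF by tumor purity and clamps the result to
#' \[0, 1\]. The correction is defined for tumor samples only; normal
#' VAFs are never corrected.
#'
#' @param raw_vaf Raw tumor VAF(s) in \[0, 1\].
#' @param purity Tumor purity in (0, 1\].
#' @return Corrected VAF(s); `NA` (with a message) where purity is
#'   missing or non-positive — such observations are excluded downstream.
#' @examples
#' corrected_vaf(0.45, 0.9)  # 0.5
#' corrected_vaf(0.6, 0.5)   # clamps to 1
#' @export
corrected_vaf <- function(raw_vaf, purity) {
  bad <- is.na(purity) | purity <= 0
  if (any(bad)) {
    inform(sprintf("%d observation(s) with missing or non-positive purity set to NA",
                   sum(bad)))
  }
  out <- ifelse(bad, NA_real_, clamp01(raw_vaf / purity))
  out
}

#' Call LOH from corrected tumor and normal VAFs
#'
#' LOH is a corrected tumor-to-normal VAF ratio at or above `threshold`
#' (default 1.6, boundary inclusive) at a carried germline heterozygous
#' locus.
#'
#' @param normal_vaf Germline VAF(s); must be > 0.
#' @param corrected Purity-corrected tumor VAF(s).
#' @param threshold Ratio threshold (default 1.6).
#' @return Tibble with `normal_vaf`, `corrected_vaf`, `ratio`, `is_loh`.
#' @export
call_loh <- function(normal_vaf, corrected, threshold = 1.6) {
  if (any(!is.na(normal_vaf) & normal_vaf <= 0)) {
    abort("normal_vaf must be > 0 (not a carried germline het)")
  }
  ratio <- corrected / normal_vaf
  tibble(normal_vaf = normal_vaf, corrected_vaf = corrected,
         ratio = ratio, is_loh = !is.na(ratio) & ratio >= threshold)
}

#' QC-filter tumor observations for LOH analysis
#'
#' Excludes observations from tumors with low purity (< `min_purity`)
#' or with low coverage at the locus (< `min_depth` reads). Boundaries
#' keep the complement: purity 0.5 and depth 10 are retained under the
#' defaults. Missing purity is excluded.
#'
#' @param observations Tibble with `purity`, `ref_reads`, `alt_reads`.
#' @param min_purity Minimum tumor purity (default 0.5).
#' @param min_depth Minimum locus read depth (default 10).
#' @return Retained observations, with attribute `filter_counts`.
#' @export
qc_tumor_observations <- function(observations, min_purity = 0.5,
                                  min_depth = 10) {
  assert_cols(observations, c("purity", "ref_reads", "alt_reads"),
              "tumor observations")
  depth <- observations$ref_reads + observations$alt_reads
  pass_purity <- !is.na(observations$purity) &
    observations$purity >= min_purity
  pass_depth <- !is.na(depth) & depth >= min_depth
  keep <- pass_purity & pass_depth
  res <- observations[keep, , drop = FALSE]
  attr(res, "filter_counts") <- tibble(
    filter = c("purity", "depth"),
    removed = c(sum(!pass_purity), sum(pass_purity & !pass_depth))
  )
  res
}

#' LOH calls for a cohort of tumor observations
#'
#' End-to-end LOH calling: joins tumor purity from the manifest, applies
#' purity/coverage QC, computes raw and purity-corrected tumor VAFs,
#' joins the germline (normal) VAF of each locus from the pDGV calls and
#' applies the ratio threshold.
#'
#' @param tumor_obs Tibble from [read_tumor_observations()].
#' @param germline Tibble with germline VAFs per (patient, locus):
#'   typically `tidy(pdgv_result)` or a background-control set; must have
#'   `patient_id`, `key` (or chrom/pos/ref/alt) and `vaf`.
#' @param tumors Tibble with `tumor_id`, `patient_id`, `site`, `purity`
#'   (e.g. `manifest$tumors`).
#' @param threshold LOH ratio threshold (default 1.6).
#' @param min_purity,min_depth QC thresholds (defaults 0.5 and 10).
#' @return Tibble, one row per retained (tumor, locus) with `site`,
#'   `purity`, read counts, `raw_vaf`, `corrected_vaf`, `normal_vaf`,
#'   `ratio`, `is_loh`; attribute `filter_counts` records QC removals.
#' @export
call_loh_cohort <- function(tumor_obs, germline, tumors, threshold = 1.6,
                            min_purity = 0.5, min_depth = 10) {
  if (!"key" %in% names(germline)) {
    germline <- mutate(germline, key = variant_key(.data$chrom, .data$pos,
                                                   .data$ref, .data$alt))
  }
  gl <- germline %>%
    select("patient_id", "key", normal_vaf = "vaf") %>%
    distinct(.data$patient_id, .data$key, .keep_all = TRUE)
  obs <- tumor_obs %>%
    inner_join(select(tumors, "tumor_id", "patient_id", "site", "purity"),
               by = "tumor_id") %>%
    inner_join(gl, by = c("patient_id", "key"))
  n_joined <- nrow(obs)
  obs <- qc_tumor_observations(obs, min_purity = min_purity,
                               min_depth = min_depth)
  qc_counts <- attr(obs, "filter_counts")
  depth <- obs$ref_reads + obs$alt_reads
  out <- obs %>%
    mutate(raw_vaf = ifelse(depth > 0, .data$alt_reads / depth, NA_real_),
           corrected_vaf = corrected_vaf(.data$raw_vaf, .data$purity),
           ratio = .data$corrected_vaf / .data$normal_vaf,
           is_loh = !is.na(.data$ratio) & .data$ratio >= threshold)
  attr(out, "filter_counts") <- qc_counts
  attr(out, "n_input") <- n_joined
  out
}

#' Background control variants for the LOH comparison
#'
#' Protein-truncating germline variants in non-TSGs whose normal VAF lies
#' in \[0.35, 0.80\] — by definition LOH concerns heterozygous loci, so
#' calls outside the heterozygous band are removed.
#'
#' @param calls Cohort germline calls.
#' @param annotations Annotation table.
#' @param roles Gene role tibble.
#' @return Tibble of control variants (same shape as annotated calls).
#' @export
build_background_controls <- function(calls, annotations, roles) {
  ann <- annotate_calls(calls, annotations)
  eff <- effective_effect(ann$effect, ann$canonical_effect)
  ann[eff %in% .truncating_effects &
        gene_role(ann$gene, roles) != "TSG" &
        !is.na(ann$vaf) & ann$vaf >= 0.35 & ann$vaf <= 0.80, , drop = FALSE]
}

#' Compare corrected-VAF distributions (TSG pDGVs vs controls)
#'
#' Two-sided Kolmogorov-Smirnov test on the purity-corrected tumor VAFs
#' of pDGVs in TSGs against truncating-variant controls in non-TSGs.
#' Exact p for small tie-free samples, asymptotic otherwise.
#'
#' @param tsg_vafs,control_vafs Numeric corrected VAFs.
#' @return List with `statistic` (D) and `p_value`.
#' @export
compare_vaf_densities <- function(tsg_vafs, control_vafs) {
  if (length(tsg_vafs) == 0 || length(control_vafs) == 0) {
    abort("both VAF samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(tsg_vafs, control_vafs,
                                        alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Paired primary-metastatic corrected-VAF comparison (deepening LOH)
#'
#' For pairs sharing a pDGV locus within a patient, reports the fraction
#' of pairs whose corrected VAF increases in the metastasis and a
#' two-sided Wilcoxon signed-rank p-value. Zero differences are dropped
#' per signed-rank convention; the exact tie-aware sign-flip null
#' distribution is used for n <= `exact_max`, the tie-corrected normal
#' approximation otherwise.
#'
#' @param primary,metastatic Numeric corrected VAFs, element i of each
#'   being the same (patient, locus).
#' @param exact_max Largest n for the exact null (default 25).
#' @return List with `fraction_increasing`, `n_pairs`, `n_nonzero`,
#'   `statistic` (V, sum of positive-difference ranks) and `p_value`.
#' @export
compare_paired_primary_met <- function(primary, metastatic,
                                       exact_max = 25) {
  if (length(primary) != length(metastatic)) {
    abort("primary and metastatic must have equal length")
  }
  if (length(primary) == 0) abort("no pairs supplied")
  d <- metastatic - primary
  frac <- mean(d > 0)
  d <- d[d != 0]
  if (length(d) == 0) {
    warn("all paired differences are zero; p-value undefined, reported as 1")
    return(list(fraction_increasing = frac, n_pairs = length(primary),
                n_nonzero = 0L, statistic = NA_real_, p_value = 1))
  }
  sr <- signed_rank_test(d, exact_max = exact_max)
  list(fraction_increasing = frac, n_pairs = length(primary),
       n_nonzero = length(d), statistic = sr$statistic,
       p_value = sr$p_value)
}

#' Exact tie-aware Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test of symmetry about zero. Ties in
#' |d| receive average ranks. For `n <= exact_max` the null distribution
#' of V (sum of ranks of positive differences) over all 2^n sign
#' assignments is computed exactly by convolution over doubled ranks;
#' p = min(1, 2 * min(P(V' <= V), P(V' >= V))). Larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param d Non-zero differences.
#' @param exact_max Exact-enumeration limit (default 25).
#' @return List with `statistic` (V), `p_value`, `exact` flag.
#' @export
signed_rank_test <- function(d, exact_max = 25) {
  d <- d[!is.na(d)]
  if (any(d == 0)) d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p_value = 1, exact = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # doubled ranks are integers even under average-rank ties
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # distribution of 2V over sign flips: polynomial product of (1 + x^r2_i)
    dist <- numeric(total + 1)  # index k+1 = P(2V = k) * 2^n
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(total + 1 - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(v2 + 1)])
    p_ge <- sum(dist[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = v, p_value = p, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    list(statistic = v, p_value = p, exact = FALSE)
  }
}
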