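# The deleterious-germline-variant filter cascade.
#
# A call survives to pDGV status iff it passes, in order: site quality,
# read depth, VAF (CHIP guard), SNV-cluster (alignment-artifact guard),
# population allele frequency, deleteriousness classification (ClinVar
# pathogenic/likely-pathogenic for a cancer or unknown condition, or
# protein-truncating in a TSG with ExAC QC), cohort recurrence
# (platform-artifact guard), and the manual-review exclusion list. Every
# input call keeps a full per-filter pass/fail trace.

.pdgv_filters <- c("quality", "depth", "vaf", "cluster", "pop_af",
                   "classification", "recurrence", "exclusion")

#' Apply per-call quality filters
#'
#' Marks each call against the profile's site-quality, depth and VAF
#' thresholds (all boundaries inclusive on the retained side; the VAF
#' floor guards against clonal hematopoiesis masquerading as germline).
#'
#' @param calls Variant-call tibble.
#' @param profile A [filter_profile()] or profile name.
#' @return `calls` with logical columns `pass_quality`, `pass_depth`,
#'   `pass_vaf` and `retained` (their conjunction) appended.
#' @export
apply_quality_filters <- function(calls, profile = "wcm") {
  profile <- as_filter_profile(profile)
  assert_cols(calls, c("site_quality", "depth", "vaf"), "calls")
  calls %>%
    mutate(
      pass_quality = !is.na(.data$site_quality) &
        .data$site_quality >= profile$min_site_quality,
      pass_depth = !is.na(.data$depth) & .data$depth >= profile$min_depth,
      pass_vaf = !is.na(.data$vaf) & .data$vaf >= profile$min_vaf,
      retained = .data$pass_quality & .data$pass_depth & .data$pass_vaf
    )
}

#' Flag SNVs in dense clusters (putative alignment artifacts)
#'
#' An SNV is flagged iff some window of `window` bp on the same chromosome
#' of the same sample contains at least `min_count` SNVs. Indels are never
#' flagged: the rule targets read-alignment artifacts, which are
#' substitution-level and per-sample phenomena.
#'
#' @param calls Variant-call tibble (may span samples; clustering is
#'   evaluated within each `sample_id`, or `patient_id` if present).
#' @param window Window width in bp (default 10).
#' @param min_count Minimum SNVs within one window to flag (default 3;
#'   `Inf` disables flagging).
#' @return Logical vector aligned with `calls` rows.
#' @export
flag_alignment_clusters <- function(calls, window = 10, min_count = 3) {
  n <- nrow(calls)
  if (n == 0 || !is.finite(min_count)) return(rep(FALSE, n))
  grp_col <- if ("patient_id" %in% names(calls)) "patient_id" else "sample_id"
  snv <- is_snv(calls$ref, calls$alt)
  flagged <- rep(FALSE, n)
  idx_all <- seq_len(n)[snv]
  if (length(idx_all) == 0) return(flagged)
  groups <- split(idx_all,
                  paste(calls[[grp_col]][idx_all], calls$chrom[idx_all]))
  for (idx in groups) {
    pos <- calls$pos[idx]
    ord <- order(pos)
    pos_s <- pos[ord]
    m <- length(pos_s)
    if (m < min_count) next
    k <- as.integer(min_count)
    in_cluster <- rep(FALSE, m)
    for (i in seq_len(m - k + 1)) {
      if (pos_s[i + k - 1] - pos_s[i] <= window - 1) {
        in_cluster[i:(i + k - 1)] <- TRUE
      }
    }
    flagged[idx[ord]] <- in_cluster
  }
  flagged
}

#' Classify annotated variants for deleteriousness
#'
#' Adds a `classification` column with one of `clinvar_pathogenic`,
#' `tsg_truncating`, `both`, `clinvar_benign`, `neutral`:
#' * ClinVar benign/likely-benign assertions are discarded outright
#'   (`clinvar_benign`), regardless of other evidence.
#' * `clinvar_pathogenic`: pathogenic/likely-pathogenic for a
#'   cancer-related or unknown condition (non-cancer conditions are
#'   excluded).
#' * `tsg_truncating`: stop-gain or frameshift on the canonical
#'   transcript (falling back to the reported effect) in a TSG, passing
#'   the ExAC inbreeding-coefficient and VQSR filters when the profile
#'   requires them.
#'
#' @param calls Annotated calls (see [annotate_calls()]).
#' @param roles Gene role tibble from [read_gene_roles()].
#' @param profile A [filter_profile()]; `require_exac_qc` and
#'   `restrict_to_tsg` are consulted.
#' @return `calls` with `role` and `classification` columns.
#' @export
classify_variants <- function(calls, roles, profile = "wcm") {
  profile <- as_filter_profile(profile)
  assert_cols(calls, c("gene", "effect", "clinvar_class"), "annotated calls")
  eff <- effective_effect(calls$effect, calls$canonical_effect)
  role <- gene_role(calls$gene, roles)
  benign <- calls$clinvar_class %in% c("benign", "likely_benign")
  cond <- calls$clinvar_condition_is_cancer
  cv_path <- calls$clinvar_class %in% c("pathogenic", "likely_pathogenic") &
    (is.na(cond) | cond)
  if (profile$restrict_to_tsg) cv_path <- cv_path & role == "TSG"
  exac_ok <- !profile$require_exac_qc |
    (calls$inbreeding_pass & calls$vqsr_pass)
  tsg_trunc <- eff %in% .truncating_effects & role == "TSG" & exac_ok
  classification <- case_when(
    benign ~ "clinvar_benign",
    cv_path & tsg_trunc ~ "both",
    cv_path ~ "clinvar_pathogenic",
    tsg_trunc ~ "tsg_truncating",
    TRUE ~ "neutral"
  )
  calls %>% mutate(role = role, classification = classification)
}

#' Call putative deleterious germline variants (pDGVs) across a cohort
#'
#' Runs the full filter cascade over per-patient germline calls and
#' returns the surviving variants with a complete per-call filter trace.
#'
#' @param calls Cohort-wide variant-call tibble with a `patient_id`
#'   column (one row per carried alt allele per patient).
#' @param annotations Annotation table from [read_annotation_table()].
#' @param roles Gene role tibble from [read_gene_roles()].
#' @param profile A [filter_profile()] or profile name.
#' @param exclusion Character vector of variant keys excluded by manual
#'   review (see [read_exclusion_list()]).
#' @param cohort_size Number of patients used as the recurrence
#'   denominator; defaults to `n_distinct(calls$patient_id)`.
#' @return An object of class `pdgv_result`: a list with
#'   * `pdgvs` — tibble of retained variants (`patient_id`, locus and
#'     sample fields, `gene`, `role`, `reason` in
#'     `clinvar_pathogenic`/`tsg_truncating`/`both`),
#'   * `trace` — one row per input call with a logical `pass_*` column
#'     per filter, `retained`, and `reason` (qualifying reason when
#'     retained, first failing filter otherwise),
#'   * `profile`, `cohort_size`.
#'   `tidy()` returns the pDGV tibble; `glance()` a one-row summary.
#' @export
call_pdgvs <- function(calls, annotations, roles, profile = "wcm",
                       exclusion = character(), cohort_size = NULL) {
  profile <- as_filter_profile(profile)
  assert_cols(calls, c("patient_id", "chrom", "pos", "ref", "alt",
                       "site_quality", "depth", "vaf", "genotype"), "calls")
  cohort_size <- cohort_size %||% n_distinct(calls$patient_id)
  if (cohort_size <= 0) abort("cohort recurrence requires cohort size > 0")

  ann <- annotate_calls(calls, annotations) %>%
    classify_variants(roles, profile)
  trace <- build_pdgv_trace(ann, profile, exclusion, cohort_size)
  pdgvs <- trace %>%
    filter(.data$retained) %>%
    select(-starts_with("pass_"), -"retained")
  structure(list(pdgvs = pdgvs, trace = trace, profile = profile,
                 cohort_size = cohort_size),
            class = "pdgv_result")
}

build_pdgv_trace <- function(ann, profile, exclusion, cohort_size) {
  qf <- apply_quality_filters(ann, profile)
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  # recurrence over raw input: carriers per distinct patient
  carriers <- ann %>%
    mutate(key = key) %>%
    distinct(.data$key, .data$patient_id) %>%
    count(.data$key, name = "n_carriers")
  n_carriers <- carriers$n_carriers[match(key, carriers$key)]
  trace <- ann %>%
    mutate(
      key = key,
      pass_quality = qf$pass_quality,
      pass_depth = qf$pass_depth,
      pass_vaf = qf$pass_vaf,
      pass_cluster = !flag_alignment_clusters(
        ann, window = profile$snv_cluster_window,
        min_count = profile$snv_cluster_min_count),
      pass_pop_af = dplyr::coalesce(.data$pop_af, 0) <= profile$max_pop_af,
      pass_classification = .data$classification %in%
        c("clinvar_pathogenic", "tsg_truncating", "both"),
      pass_recurrence = n_carriers / cohort_size <=
        profile$cohort_recurrence_max,
      pass_exclusion = !key %in% exclusion
    )
  pass_mat <- as.matrix(select(trace, all_of(paste0("pass_", .pdgv_filters))))
  retained <- rowSums(!pass_mat) == 0
  first_fail <- apply(pass_mat, 1, function(p) {
    i <- which(!p)[1]
    if (is.na(i)) NA_character_ else .pdgv_filters[i]
  })
  trace %>%
    mutate(retained = retained,
           reason = ifelse(retained, .data$classification, first_fail))
}

#' @export
print.pdgv_result <- function(x, ...) {
  cat(sprintf("<pdgv_result: %d pDGV(s) from %d call(s), %d patient(s), profile '%s'>\n",
              nrow(x$pdgvs), nrow(x$trace), x$cohort_size, x$profile$name))
  print(filter_summary(x))
  invisible(x)
}

#' Tidy a pDGV result
#' @param x A `pdgv_result`.
#' @param ... Unused.
#' @return The tibble of retained pDGVs.
#' @method tidy pdgv_result
#' @export
tidy.pdgv_result <- function(x, ...) x$pdgvs

#' One-row summary of a pDGV result
#' @param x A `pdgv_result`.
#' @param ... Unused.
#' @return Tibble with input/output counts, carriers and the per-patient
#'   median pDGV count.
#' @method glance pdgv_result
#' @export
glance.pdgv_result <- function(x, ...) {
  per_patient <- x$trace %>%
    distinct(.data$patient_id) %>%
    left_join(count(x$pdgvs, .data$patient_id), by = "patient_id") %>%
    mutate(n = replace_na(.data$n, 0L))
  tibble(
    n_input = nrow(x$trace),
    n_pdgv = nrow(x$pdgvs),
    n_patients = x$cohort_size,
    n_carriers = n_distinct(x$pdgvs$patient_id),
    median_pdgv_per_patient = stats::median(per_patient$n),
    profile = x$profile$name
  )
}

#' Per-filter removal counts for a pDGV result
#'
#' Attributes each removed call to its first failing filter, so counts
#' satisfy `n_input = n_retained + sum(removed)`.
#'
#' @param x A `pdgv_result`.
#' @return Tibble with `filter`, `removed`.
#' @export
filter_summary <- function(x) {
  stopifnot(inherits(x, "pdgv_result"))
  removed <- x$trace %>%
    filter(!.data$retained) %>%
    count(.data$reason, name = "removed")
  tibble(filter = .pdgv_filters) %>%
    left_join(removed, by = c(filter = "reason")) %>%
    mutate(removed = replace_na(.data$removed, 0L))
}

#' Extract rare synonymous variants under matched QC
#'
#' The burden-test denominator: synonymous variants (canonical transcript
#' first) with population allele frequency below 1% that pass the same
#' quality, depth, VAF, SNV-cluster, ExAC-QC and cohort-recurrence
#' filters as the deleterious-variant cascade. Variants absent from the
#' population database count as rare.
#'
#' @inheritParams call_pdgvs
#' @return Tibble of retained synonymous calls (per patient), with an
#'   attribute `filter_counts` recording per-filter removals among
#'   synonymous candidates.
#' @export
extract_rare_synonymous <- function(calls, annotations, roles,
                                    profile = "wcm", cohort_size = NULL) {
  profile <- as_filter_profile(profile)
  cohort_size <- cohort_size %||% n_distinct(calls$patient_id)
  if (cohort_size <= 0) abort("cohort recurrence requires cohort size > 0")
  ann <- annotate_calls(calls, annotations)
  # cluster flags are a property of the whole sample, not the synonymous
  # subset, so compute them before subsetting
  cluster_flag <- flag_alignment_clusters(
    ann, window = profile$snv_cluster_window,
    min_count = profile$snv_cluster_min_count)
  eff <- effective_effect(ann$effect, ann$canonical_effect)
  syn <- ann[eff == "synonymous", , drop = FALSE]
  cluster_flag <- cluster_flag[eff == "synonymous"]
  if (nrow(syn) == 0) {
    res <- syn
    attr(res, "filter_counts") <- tibble(filter = character(),
                                         removed = integer())
    return(res)
  }
  qf <- apply_quality_filters(syn, profile)
  pass <- tibble(
    pop_af = dplyr::coalesce(syn$pop_af, 0) < 0.01,
    quality = qf$pass_quality,
    depth = qf$pass_depth,
    vaf = qf$pass_vaf,
    cluster = !cluster_flag,
    exac_qc = !profile$require_exac_qc |
      (syn$inbreeding_pass & syn$vqsr_pass)
  )
  key <- variant_key(syn$chrom, syn$pos, syn$ref, syn$alt)
  carriers <- syn %>%
    mutate(key = key) %>%
    distinct(.data$key, .data$patient_id) %>%
    count(.data$key, name = "n_carriers")
  pass$recurrence <- carriers$n_carriers[match(key, carriers$key)] /
    cohort_size <= profile$cohort_recurrence_max
  keep <- rowSums(!as.matrix(pass)) == 0
  first_fail <- apply(as.matrix(pass), 1, function(p) {
    i <- which(!p)[1]
    if (is.na(i)) NA_character_ else names(pass)[i]
  })
  res <- syn[keep, , drop = FALSE]
  attr(res, "filter_counts") <- tibble(filter = first_fail[!keep]) %>%
    count(.data$filter, name = "removed")
  res
}
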