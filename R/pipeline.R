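# End-to-end orchestration over a cohort bundle.

#' Run the full germline-somatic pipeline over a cohort bundle
#'
#' Executes the stages in dependency order: germline filter cascade,
#' rare-synonymous extraction, background-control construction,
#' LOH calling (pDGVs and controls), somatic consensus + filtering, and
#' gene-/pathway-level interaction detection. Any stage failure aborts
#' with the stage name.
#'
#' @param cohort A bundle directory path, or a list as returned by
#'   [simulate_cohort()] / [read_cohort()].
#' @param profile Filter profile or name (default: the manifest's).
#' @param loh_threshold LOH ratio threshold (default 1.6).
#' @param alpha Pathway-GSI significance threshold (default 0.05).
#' @param exclusion Variant exclusion keys (default: the bundle's list,
#'   if any).
#' @return List of class `dgv_run`: `pdgvs` (`pdgv_result`),
#'   `rare_synonymous`, `controls`, `loh`, `loh_controls`, `somatic`,
#'   `gene_gsi`, `pathway_gsi` and `report` (a [run_report()] list).
#' @export
run_dgvar <- function(cohort, profile = NULL, loh_threshold = 1.6,
                      alpha = 0.05, exclusion = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  profile <- as_filter_profile(profile %||% cohort$manifest$filter_profile)
  exclusion <- exclusion %||% cohort$exclusion %||% character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  pdgvs <- stage("call_pdgvs", call_pdgvs(
    cohort$calls, cohort$annotations, cohort$roles, profile,
    exclusion = exclusion,
    cohort_size = nrow(cohort$manifest$patients)))
  rare_syn <- stage("rare_synonymous", extract_rare_synonymous(
    cohort$calls, cohort$annotations, cohort$roles, profile,
    cohort_size = nrow(cohort$manifest$patients)))
  controls <- stage("background_controls", build_background_controls(
    cohort$calls, cohort$annotations, cohort$roles))
  tumors <- cohort$manifest$tumors
  loh <- stage("loh", call_loh_cohort(
    cohort$tumor_obs, pdgvs$pdgvs, tumors, threshold = loh_threshold))
  loh_controls <- stage("loh_controls", call_loh_cohort(
    cohort$tumor_obs, controls, tumors, threshold = loh_threshold))
  somatic <- stage("somatic_consensus", {
    consensus <- merge_callers(cohort$caller_calls)
    apply_somatic_filters(consensus)
  })
  gene_gsi <- stage("gene_gsi", gene_level_gsi(
    pdgvs, somatic, cohort$cn_events, cohort$annotations, cohort$roles,
    tumors))
  pathway_gsi <- stage("pathway_gsi", pathway_level_gsi(
    pdgvs, somatic, cohort$cn_events, cohort$pathways,
    cohort$annotations, cohort$roles, tumors, alpha = alpha))
  res <- list(pdgvs = pdgvs, rare_synonymous = rare_syn,
              controls = controls, loh = loh, loh_controls = loh_controls,
              somatic = somatic, gene_gsi = gene_gsi,
              pathway_gsi = pathway_gsi, profile = profile)
  res$report <- run_report(res, cohort)
  structure(res, class = "dgv_run")
}

#' Build the per-stage run report
#'
#' Per-stage input/removal/output counts (each stage's removals sum to
#' input minus output), per-patient pDGV median, LOH and interaction
#' tallies, plus a digest of the inputs and package version for
#' reproducibility checks.
#'
#' @param run A partially assembled `dgv_run` list.
#' @param cohort The cohort inputs the run consumed.
#' @return List with `stages` (tibble), `summary` (tibble) and `digest`.
#' @export
run_report <- function(run, cohort) {
  pdgv_counts <- filter_summary(run$pdgvs)
  syn_counts <- attr(run$rare_synonymous, "filter_counts")
  loh_counts <- attr(run$loh, "filter_counts")
  som_counts <- bind_rows(attr(run$somatic, "filter_counts"))
  stages <- bind_rows(
    tibble(stage = "pdgv", filter = pdgv_counts$filter,
           removed = pdgv_counts$removed),
    tibble(stage = "rare_synonymous", filter = syn_counts$filter,
           removed = syn_counts$removed),
    tibble(stage = "loh_qc", filter = loh_counts$filter,
           removed = loh_counts$removed),
    tibble(stage = "somatic", filter = som_counts$filter,
           removed = som_counts$removed)
  )
  g <- glance(run$pdgvs)
  summary <- tibble(
    n_patients = g$n_patients,
    n_germline_calls = nrow(run$pdgvs$trace),
    n_pdgvs = g$n_pdgv,
    n_pdgv_carriers = g$n_carriers,
    median_pdgv_per_patient = g$median_pdgv_per_patient,
    n_rare_synonymous = nrow(run$rare_synonymous),
    n_loh_observations = nrow(run$loh),
    n_loh_calls = sum(run$loh$is_loh),
    loh_fraction = ifelse(nrow(run$loh) > 0,
                          mean(run$loh$is_loh), NA_real_),
    n_somatic = nrow(run$somatic),
    n_gene_gsi = nrow(run$gene_gsi),
    n_pathway_gsi = nrow(run$pathway_gsi)
  )
  digest <- rlang::hash(list(
    calls = cohort$calls, annotations = cohort$annotations,
    profile = unclass(run$profile), summary = summary))
  list(stages = stages, summary = summary, digest = digest,
       package_version = as.character(utils::packageVersion("dgvar")))
}

#' @export
print.dgv_run <- function(x, ...) {
  cat("<dgv_run>\n")
  print(x$report$summary)
  invisible(x)
}

#' @rdname run_dgvar
#' @param x A `dgv_run`.
#' @param ... Unused.
#' @method glance dgv_run
#' @export
glance.dgv_run <- function(x, ...) x$report$summary
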