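# Germline-somatic interactions (GSIs) at the gene and pathway level,
# the pathway enrichment score, and intra-patient private-GSI summaries.

#' Pathway enrichment score for deleterious germline variants
#'
#' `log10(1000 * g / (G * P) + 1)` where `g` is the number of genes with
#' deleterious germline variants in the pathway, `G` the number of such
#' genes in the patient, and `P` the pathway size. Zero when the pathway
#' holds no affected gene; strictly increasing in `g` and decreasing in
#' `G` and `P`.
#'
#' @param n_pathway_dgv_genes,n_patient_dgv_genes,n_pathway_genes
#'   Non-negative integers (vectorized); the two denominator terms must
#'   be positive.
#' @return Numeric score(s), always >= 0.
#' @examples
#' enrichment_score(2, 4, 50)  # log10(11)
#' @export
enrichment_score <- function(n_pathway_dgv_genes, n_patient_dgv_genes,
                             n_pathway_genes) {
  if (any(n_patient_dgv_genes <= 0) || any(n_pathway_genes <= 0)) {
    abort("patient gene count and pathway size must be positive")
  }
  if (any(n_pathway_dgv_genes < 0)) abort("gene counts must be >= 0")
  log10(1000 * n_pathway_dgv_genes /
          (n_patient_dgv_genes * n_pathway_genes) + 1)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a query gene set and a pathway, drawing `|query|` genes
#' without replacement from a universe containing `|pathway|` successes.
#'
#' @param query_genes,pathway_genes,universe Character vectors of gene
#'   symbols; query and pathway are intersected with the universe.
#' @return Upper-tail p-value `P(X >= overlap)`.
#' @export
ora_test <- function(query_genes, pathway_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe")
  query <- intersect(unique(query_genes), universe)
  pathway <- intersect(unique(pathway_genes), universe)
  k <- length(intersect(query, pathway))
  stats::phyper(k - 1, length(pathway),
                length(universe) - length(pathway), length(query),
                lower.tail = FALSE)
}

# Somatic gene events qualifying for GSI analysis: truncating mutations
# or copy-number losses in TSGs, non-truncating mutations in oncogenes.
qualifying_somatic_genes <- function(somatic, cn_events, annotations, roles) {
  empty_events <- tibble(tumor_id = character(), gene = character(),
                         role = character(), event = character())
  mut <- if (nrow(somatic) == 0) empty_events else somatic %>%
    left_join(select(annotations, "chrom", "pos", "ref", "alt", "gene",
                     ann_effect = "effect",
                     ann_canonical = "canonical_effect"),
              by = c("chrom", "pos", "ref", "alt")) %>%
    mutate(effect = effective_effect(.data$ann_effect, .data$ann_canonical),
           role = gene_role(.data$gene, roles)) %>%
    filter(!is.na(.data$gene)) %>%
    filter((.data$role == "TSG" & .data$effect %in% .truncating_effects) |
             (.data$role == "oncogene" &
                !.data$effect %in% .truncating_effects)) %>%
    transmute(.data$tumor_id, .data$gene, .data$role,
              event = if_else(.data$role == "TSG", "truncating_mutation",
                              "nontruncating_mutation"))
  cn <- if (is.null(cn_events) || nrow(cn_events) == 0) {
    empty_events
  } else {
    cn_events %>%
      filter(.data$direction == "loss") %>%
      mutate(role = gene_role(.data$gene, roles)) %>%
      filter(.data$role == "TSG") %>%
      transmute(.data$tumor_id, .data$gene, .data$role, event = "cn_loss")
  }
  bind_rows(mut, cn)
}

#' Gene-level germline-somatic interactions
#'
#' One record per (tumor, TSG) where a pDGV coexists with a qualifying
#' somatic second hit in the same gene: a truncating somatic mutation or
#' a somatic copy-number loss.
#'
#' @param pdgvs pDGV tibble (or `pdgv_result`).
#' @param somatic Filtered consensus somatic calls.
#' @param cn_events Gene-level copy-number events ([read_cn_events()]).
#' @param annotations Annotation table (provides somatic gene/effect).
#' @param roles Gene role tibble.
#' @param tumors Tibble mapping `tumor_id` to `patient_id`.
#' @return Tibble with `patient_id`, `tumor_id`, `gene`, `germline_key`,
#'   `somatic_event`.
#' @export
gene_level_gsi <- function(pdgvs, somatic, cn_events, annotations, roles,
                           tumors) {
  if (inherits(pdgvs, "pdgv_result")) pdgvs <- pdgvs$pdgvs
  som <- qualifying_somatic_genes(somatic, cn_events, annotations, roles) %>%
    filter(.data$role == "TSG",
           .data$event %in% c("truncating_mutation", "cn_loss")) %>%
    inner_join(select(tumors, "tumor_id", "patient_id"), by = "tumor_id")
  germ <- pdgvs %>%
    filter(gene_role(.data$gene, roles) == "TSG") %>%
    transmute(.data$patient_id, .data$gene,
              germline_key = variant_key(.data$chrom, .data$pos,
                                         .data$ref, .data$alt))
  inner_join(som, germ, by = c("patient_id", "gene")) %>%
    transmute(.data$patient_id, .data$tumor_id, .data$gene,
              .data$germline_key, somatic_event = .data$event) %>%
    distinct()
}

# Collapse pathways sharing an identical gene set (same pathway sourced
# from several collections).
merge_identical_pathways <- function(pathways) {
  sig <- purrr::map_chr(pathways$genes,
                        function(g) paste(sort(unique(g)), collapse = "|"))
  pathways %>%
    mutate(.sig = sig) %>%
    group_by(.data$.sig) %>%
    summarise(pathway_id = first(.data$pathway_id),
              name = paste(unique(.data$name), collapse = ";"),
              genes = list(sort(unique(unlist(.data$genes)))),
              .groups = "drop") %>%
    select("pathway_id", "name", "genes")
}

#' Pathway-level germline-somatic interactions
#'
#' Per tumor-normal pair, combines the patient's pDGV genes with the
#' tumor's qualifying somatic genes (truncating/CN-loss in TSGs,
#' non-truncating in oncogenes), tests each pathway for
#' over-representation of the combined gene set, and emits an
#' interaction for every pathway with p below `alpha` that contains at
#' least one germline and one somatic gene. Pathways with identical gene
#' sets (the same pathway from different source collections) are merged
#' first.
#'
#' @inheritParams gene_level_gsi
#' @param pathways Pathway tibble from [read_gene_sets()].
#' @param universe Gene universe for the hypergeometric test; default
#'   all genes in the annotation table union the role list.
#' @param alpha Significance threshold, strict (default 0.05).
#' @param allowlist Optional pathway-id allow-list (curated
#'   cancer-associated pathways); default all.
#' @param adjust Multiple-testing adjustment applied per tumor before
#'   thresholding (`"none"` by default, any [stats::p.adjust()] method).
#' @return Tibble with `patient_id`, `tumor_id`, `pathway_id`,
#'   `germline_genes` and `somatic_genes` list-columns, `p_value` and a
#'   `private` flag (no other tumor of the same patient shares the
#'   pathway).
#' @export
pathway_level_gsi <- function(pdgvs, somatic, cn_events, pathways,
                              annotations, roles, tumors,
                              universe = NULL, alpha = 0.05,
                              allowlist = NULL, adjust = "none") {
  if (inherits(pdgvs, "pdgv_result")) pdgvs <- pdgvs$pdgvs
  universe <- universe %||% unique(c(annotations$gene, roles$gene))
  universe <- universe[!is.na(universe)]
  pw <- merge_identical_pathways(pathways)
  if (!is.null(allowlist)) pw <- filter(pw, .data$pathway_id %in% allowlist)
  som <- qualifying_somatic_genes(somatic, cn_events, annotations, roles) %>%
    inner_join(select(tumors, "tumor_id", "patient_id"), by = "tumor_id")
  germ_by_patient <- pdgvs %>%
    filter(!is.na(.data$gene)) %>%
    distinct(.data$patient_id, .data$gene)

  out <- purrr::map_dfr(unique(som$tumor_id), function(tid) {
    pid <- tumors$patient_id[match(tid, tumors$tumor_id)]
    g_genes <- germ_by_patient$gene[germ_by_patient$patient_id == pid]
    s_genes <- unique(som$gene[som$tumor_id == tid])
    if (length(g_genes) == 0 || length(s_genes) == 0) return(NULL)
    query <- unique(c(g_genes, s_genes))
    hits <- purrr::pmap_dfr(pw, function(pathway_id, name, genes) {
      g_in <- intersect(g_genes, genes)
      s_in <- intersect(s_genes, genes)
      if (length(g_in) == 0 || length(s_in) == 0) return(NULL)
      tibble(pathway_id = pathway_id,
             germline_genes = list(sort(g_in)),
             somatic_genes = list(sort(s_in)),
             p_value = ora_test(query, genes, universe))
    })
    if (nrow(hits) == 0) return(NULL)
    hits$p_adj <- stats::p.adjust(hits$p_value, method = adjust)
    hits %>%
      filter(.data$p_adj < alpha) %>%
      mutate(patient_id = pid, tumor_id = tid, .before = 1) %>%
      select(-"p_adj")
  })
  if (nrow(out) == 0) {
    return(tibble(patient_id = character(), tumor_id = character(),
                  pathway_id = character(), germline_genes = list(),
                  somatic_genes = list(), p_value = double(),
                  private = logical()))
  }
  flag_private_gsi(out)
}

# private = the pathway appears in no other tumor of the same patient
flag_private_gsi <- function(gsis) {
  gsis %>%
    group_by(.data$patient_id, .data$pathway_id) %>%
    mutate(private = n_distinct(.data$tumor_id) == 1) %>%
    ungroup()
}

#' Fraction of tumors carrying a private pathway-level GSI
#'
#' Among tumors of patients with at least two analyzed tumors, the
#' fraction possessing at least one pathway-level interaction whose
#' pathway appears in no other tumor of the same patient. Set
#' `multi_tumor_only = FALSE` to use all tumors as the denominator.
#'
#' @param gsis Tibble from [pathway_level_gsi()].
#' @param tumors Tumor-to-patient mapping (defines the denominator).
#' @param multi_tumor_only Restrict the denominator to tumors of
#'   multi-tumor patients (default TRUE).
#' @return Fraction in \[0, 1\].
#' @export
private_gsi_fraction <- function(gsis, tumors, multi_tumor_only = TRUE) {
  denom <- tumors
  if (multi_tumor_only) {
    denom <- denom %>%
      group_by(.data$patient_id) %>%
      filter(n() >= 2) %>%
      ungroup()
  }
  if (nrow(denom) == 0) abort("no tumors in the denominator")
  gsis <- flag_private_gsi(gsis)
  private_tumors <- gsis %>%
    filter(.data$private, .data$tumor_id %in% denom$tumor_id) %>%
    distinct(.data$tumor_id)
  nrow(private_tumors) / nrow(denom)
}
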