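# Delimited-text inputs: variant annotations, gene roles, pathway gene
# sets (GMT), cohort manifest, tumor observations, copy-number events,
# exclusion lists.

#' Read the per-variant annotation table
#'
#' Tab-delimited, one row per (chrom, pos, ref, alt) with functional,
#' clinical and population metadata: `gene`, `effect`, `canonical_effect`
#' (effect on the longest-CDS transcript; may be empty), `clinvar_class`,
#' `clinvar_condition_is_cancer` (TRUE/FALSE/NA), `pop_af` (population
#' allele frequency; empty means not observed), `inbreeding_pass`,
#' `vqsr_pass`, `cadd_phred` (may be empty), `dbsnp`, `cosmic`.
#'
#' @param path TSV path with a header row naming all fields.
#' @return Tibble keyed by `key = chrom:pos:ref:alt` (unique).
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           chrom = "c", pos = "i", ref = "c", alt = "c",
                           gene = "c", effect = "c", canonical_effect = "c",
                           clinvar_class = "c",
                           clinvar_condition_is_cancer = "l",
                           pop_af = "d", inbreeding_pass = "l",
                           vqsr_pass = "l", cadd_phred = "d",
                           dbsnp = "l", cosmic = "l"))
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  assert_cols(ann, c("chrom", "pos", "ref", "alt", "gene", "effect",
                     "clinvar_class", "pop_af", "inbreeding_pass",
                     "vqsr_pass"), "annotation table")
  if (!"canonical_effect" %in% names(ann)) ann$canonical_effect <- NA_character_
  if (!"clinvar_condition_is_cancer" %in% names(ann)) {
    ann$clinvar_condition_is_cancer <- NA
  }
  if (!"cadd_phred" %in% names(ann)) ann$cadd_phred <- NA_real_
  if (!"dbsnp" %in% names(ann)) ann$dbsnp <- FALSE
  if (!"cosmic" %in% names(ann)) ann$cosmic <- FALSE
  bad_eff <- setdiff(unique(c(ann$effect, ann$canonical_effect)),
                     c(.effect_levels, NA))
  if (length(bad_eff) > 0) {
    abort(sprintf("unknown effect class: %s", paste(bad_eff, collapse = ", ")))
  }
  bad_cv <- setdiff(unique(ann$clinvar_class), c(.clinvar_levels, NA))
  if (length(bad_cv) > 0) {
    abort(sprintf("unknown clinvar_class: %s", paste(bad_cv, collapse = ", ")))
  }
  bad_af <- which(!is.na(ann$pop_af) & (ann$pop_af < 0 | ann$pop_af > 1))
  if (length(bad_af) > 0) {
    abort(sprintf("pop_af outside [0,1] at row(s) %s",
                  paste(head(bad_af, 5), collapse = ", ")))
  }
  ann <- mutate(ann,
                clinvar_class = replace_na(.data$clinvar_class, "absent"),
                key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  dup <- ann$key[duplicated(ann$key)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate annotation key(s): %s",
                  paste(unique(head(dup, 5)), collapse = ", ")))
  }
  ann
}

# The defined annotation for a variant absent from the table: no gene, no
# ClinVar assertion, population frequency unobserved, ExAC QC not passed.
absent_annotation <- function() {
  tibble(gene = NA_character_, effect = "other",
         canonical_effect = NA_character_, clinvar_class = "absent",
         clinvar_condition_is_cancer = NA, pop_af = NA_real_,
         inbreeding_pass = FALSE, vqsr_pass = FALSE, cadd_phred = NA_real_,
         dbsnp = FALSE, cosmic = FALSE)
}

#' Join annotations onto variant calls
#'
#' Left-joins the annotation table onto calls by (chrom, pos, ref, alt);
#' unannotated variants receive the absent-annotation sentinel (ClinVar
#' `"absent"`, `pop_af` missing, effect `"other"`) rather than an error.
#'
#' @param calls Variant-call tibble.
#' @param annotations Tibble from [read_annotation_table()].
#' @return `calls` with annotation columns appended.
#' @export
annotate_calls <- function(calls, annotations) {
  sentinel <- absent_annotation()
  out <- left_join(calls, select(annotations, -"key"),
                   by = c("chrom", "pos", "ref", "alt"))
  out %>%
    mutate(
      effect = ifelse(is.na(.data$effect), sentinel$effect, .data$effect),
      clinvar_class = replace_na(.data$clinvar_class, sentinel$clinvar_class),
      inbreeding_pass = replace_na(.data$inbreeding_pass, FALSE),
      vqsr_pass = replace_na(.data$vqsr_pass, FALSE),
      dbsnp = replace_na(.data$dbsnp, FALSE),
      cosmic = replace_na(.data$cosmic, FALSE)
    )
}

#' Read the gene role list
#'
#' Two-column TSV (`gene`, `role`) assigning each gene `TSG` or
#' `oncogene`. Genes annotated with both roles resolve to `TSG`.
#'
#' @param path TSV path.
#' @return Tibble with unique `gene` and `role`.
#' @export
read_gene_roles <- function(path) {
  roles <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(gene = "c", role = "c"))
  validate_gene_roles(roles)
}

validate_gene_roles <- function(roles) {
  assert_cols(roles, c("gene", "role"), "gene role table")
  bad <- setdiff(unique(roles$role), c("TSG", "oncogene"))
  if (length(bad) > 0) {
    abort(sprintf("unknown gene role: %s", paste(bad, collapse = ", ")))
  }
  roles %>%
    group_by(.data$gene) %>%
    summarise(role = if (any(.data$role == "TSG")) "TSG" else "oncogene",
              .groups = "drop")
}

gene_role <- function(genes, roles) {
  idx <- match(genes, roles$gene)
  ifelse(is.na(idx), "none", roles$role[idx])
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT (id, description, genes...). Duplicate genes within a line
#' are deduplicated; duplicate pathway ids or lines without any gene are
#' errors.
#'
#' @param path GMT path.
#' @return Tibble with `pathway_id`, `name` and a `genes` list-column of
#'   unique gene symbols.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    abort(sprintf("duplicate pathway id(s): %s",
                  paste(unique(names(sets)[duplicated(names(sets))]),
                        collapse = ", ")))
  }
  sets <- purrr::map(sets, function(g) unique(g[!is.na(g) & g != ""]))
  n_genes <- purrr::map_int(sets, length)
  if (any(n_genes == 0)) {
    abort(sprintf("pathway(s) with no genes: %s",
                  paste(names(sets)[n_genes == 0], collapse = ", ")))
  }
  tibble(pathway_id = names(sets), name = names(sets),
         genes = unname(sets))
}

#' Write pathway gene sets to a GMT file
#' @param pathways Tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(pathways, path) {
  lines <- purrr::pmap_chr(
    list(pathways$pathway_id, pathways$name, pathways$genes),
    function(id, name, genes) paste(c(id, name, genes), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read the cohort manifest
#'
#' YAML file binding patients to germline samples and tumors. Layout:
#' ```yaml
#' filter_profile: wcm
#' patients:
#'   - patient_id: P01
#'     ethnicity: EUR
#'     germline_sample: P01_N
#'     tumors:
#'       - {tumor_id: P01_T1, site: primary, purity: 0.72}
#' ```
#' Tumor `purity` may be omitted (the tumor is then excluded from LOH by
#' QC); `purity_source` defaults to `"clonet"`.
#'
#' @param path YAML manifest path.
#' @return List of class `cohort_manifest` with tibbles `$patients`
#'   (`patient_id`, `ethnicity`, `germline_sample`) and `$tumors`
#'   (`tumor_id`, `patient_id`, `site`, `purity`, `purity_source`), plus
#'   `$filter_profile`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$patients)) abort(sprintf("manifest %s has no patients", path))
  # [[ ]] lookups: $ would partially match (e.g. purity -> purity_source)
  patients <- purrr::map_dfr(raw$patients, function(p) {
    tibble(patient_id = p[["patient_id"]],
           ethnicity = p[["ethnicity"]] %||% NA_character_,
           germline_sample = p[["germline_sample"]] %||% p[["patient_id"]])
  })
  tumors <- purrr::map_dfr(raw$patients, function(p) {
    purrr::map_dfr(p[["tumors"]], function(t) {
      site <- t[["site"]] %||% "primary"
      if (!site %in% c("primary", "metastatic")) {
        abort(sprintf("tumor %s has unknown site '%s'", t[["tumor_id"]], site))
      }
      tibble(tumor_id = t[["tumor_id"]], patient_id = p[["patient_id"]],
             site = site,
             purity = as.numeric(t[["purity"]] %||% NA_real_),
             purity_source = t[["purity_source"]] %||% "clonet")
    })
  })
  if (nrow(tumors) > 0) {
    orphan <- setdiff(tumors$patient_id, patients$patient_id)
    if (length(orphan) > 0) {
      abort(sprintf("tumors reference unknown patient(s): %s",
                    paste(orphan, collapse = ", ")))
    }
    bad_p <- tumors$purity[!is.na(tumors$purity)]
    if (any(bad_p < 0 | bad_p > 1)) abort("tumor purity outside [0,1]")
  }
  structure(list(patients = patients, tumors = tumors,
                 filter_profile = raw$filter_profile %||% "wcm"),
            class = "cohort_manifest")
}

#' Write a cohort manifest to YAML
#' @param manifest `cohort_manifest` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  pats <- purrr::pmap(manifest$patients, function(patient_id, ethnicity,
                                                  germline_sample) {
    tums <- manifest$tumors %>% filter(.data$patient_id == !!patient_id)
    list(patient_id = patient_id, ethnicity = ethnicity,
         germline_sample = germline_sample,
         tumors = purrr::pmap(
           select(tums, "tumor_id", "site", "purity", "purity_source"),
           function(tumor_id, site, purity, purity_source) {
             out <- list(tumor_id = tumor_id, site = site,
                         purity_source = purity_source)
             if (!is.na(purity)) out$purity <- purity
             out
           }))
  })
  yaml::write_yaml(list(filter_profile = manifest$filter_profile,
                        patients = pats), path)
  invisible(path)
}

#' Read forced tumor read counts at germline loci
#'
#' TSV with `tumor_id`, `chrom`, `pos`, `ref`, `alt`, `ref_reads`,
#' `alt_reads`: the joint re-genotyping of every germline locus of
#' interest in every tumor, regardless of the tumor's own genotype call.
#'
#' @param path TSV path.
#' @return Tibble with a `key` column added.
#' @export
read_tumor_observations <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           tumor_id = "c", chrom = "c", pos = "i",
                           ref = "c", alt = "c", ref_reads = "i",
                           alt_reads = "i"))
  assert_cols(obs, c("tumor_id", "chrom", "pos", "ref", "alt",
                     "ref_reads", "alt_reads"), "tumor observations")
  mutate(obs, key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
}

#' Read gene-level somatic copy-number events
#' @param path TSV with `tumor_id`, `gene`, `direction` (`loss`/`gain`).
#' @return Tibble, one row per (tumor, gene, direction).
#' @export
read_cn_events <- function(path) {
  cn <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(tumor_id = "c", gene = "c",
                                                direction = "c"))
  assert_cols(cn, c("tumor_id", "gene", "direction"), "copy-number events")
  bad <- setdiff(unique(cn$direction), c("loss", "gain"))
  if (length(bad) > 0) abort(sprintf("unknown CN direction: %s", bad[1]))
  distinct(cn)
}

#' Read a variant exclusion list
#'
#' Declarative replacement for manual review: variants keyed by
#' (chrom, pos, ref, alt) that are removed from the deleterious-variant
#' calls regardless of other filters.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt` (may be empty
#'   apart from the header).
#' @return Character vector of variant keys.
#' @export
read_exclusion_list <- function(path) {
  ex <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(chrom = "c", pos = "i",
                                                ref = "c", alt = "c"))
  if (nrow(ex) == 0) return(character())
  variant_key(ex$chrom, ex$pos, ex$ref, ex$alt)
}
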