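# Builders for small in-code fixtures.

make_call <- function(patient_id = "P1", chrom = "chr1", pos = 1000L,
                      ref = "A", alt = "T", site_quality = 99,
                      depth = 60L, alt_depth = 29L, genotype = "het",
                      vaf = NULL) {
  tibble::tibble(
    patient_id = patient_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, site_quality = site_quality,
    depth = as.integer(depth), alt_depth = as.integer(alt_depth),
    genotype = genotype,
    vaf = vaf %||% (alt_depth / depth)
  )
}

make_ann <- function(calls, gene = "TSG1", effect = "stop_gained",
                     canonical_effect = NA_character_,
                     clinvar_class = "absent",
                     clinvar_condition_is_cancer = NA,
                     pop_af = 0.0005, inbreeding_pass = TRUE,
                     vqsr_pass = TRUE, cadd_phred = NA_real_,
                     dbsnp = FALSE, cosmic = FALSE) {
  ann <- dplyr::distinct(calls, chrom, pos, ref, alt)
  n <- nrow(ann)
  ann$gene <- rep_len(gene, n)
  ann$effect <- rep_len(effect, n)
  ann$canonical_effect <- rep_len(canonical_effect, n)
  ann$clinvar_class <- rep_len(clinvar_class, n)
  ann$clinvar_condition_is_cancer <- rep_len(clinvar_condition_is_cancer, n)
  ann$pop_af <- rep_len(pop_af, n)
  ann$inbreeding_pass <- rep_len(inbreeding_pass, n)
  ann$vqsr_pass <- rep_len(vqsr_pass, n)
  ann$cadd_phred <- rep_len(cadd_phred, n)
  ann$dbsnp <- rep_len(dbsnp, n)
  ann$cosmic <- rep_len(cosmic, n)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

basic_roles <- function() {
  tibble::tibble(gene = c("TSG1", "TSG2", "ONC1"),
                 role = c("TSG", "TSG", "oncogene"))
}

make_somatic_call <- function(tumor_id = "T1", caller = "mutect2",
                              chrom = "chr1", pos = 100L, ref = "A",
                              alt = "T", tumor_depth = 80L,
                              tumor_alt = 20L, normal_vaf = 0,
                              dbsnp = FALSE, cosmic = FALSE) {
  tibble::tibble(tumor_id = tumor_id, caller = caller, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 tumor_depth = as.integer(tumor_depth),
                 tumor_alt = as.integer(tumor_alt),
                 tumor_vaf = tumor_alt / tumor_depth,
                 normal_vaf = normal_vaf, dbsnp = dbsnp, cosmic = cosmic)
}

write_lines_vcf <- function(records, path,
                            sample = "S1",
                            format_lines = c(
                              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")) {
  writeLines(c("##fileformat=VCFv4.2", format_lines,
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample),
               records), path)
  path
}

`%||%` <- rlang::`%||%`
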