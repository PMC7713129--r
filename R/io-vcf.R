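# Germline and somatic-caller VCF input/output.
#
# Parsing is delegated to vcfR; these wrappers decompose multiallelic
# records into one row per alt allele and compute per-allele depths and
# VAFs from the AD field, which is the representation every downstream
# stage works with.

#' Read a single-sample germline VCF into a variant-call tibble
#'
#' Reads a VCF 4.x file and returns one row per carried alternate allele
#' for `sample_id`. Multiallelic records are decomposed so each row holds
#' exactly one alt allele; depth is the sum of all AD fields at the site,
#' `alt_depth` the AD entry of that allele, and `vaf = alt_depth / depth`.
#' Genotypes `0/0` and `./.` are dropped: only carried alternative alleles
#' matter for germline analysis.
#'
#' @param path Path to a VCF file with GT and AD FORMAT fields.
#' @param sample_id Sample column to read; defaults to the first sample.
#' @return A tibble with columns `sample_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `site_quality`, `depth`, `alt_depth`, `genotype`
#'   (`"het"` or `"hom_alt"`) and `vaf`, sorted by (`chrom`, `pos`).
#' @examples
#' calls <- read_vcf(system.file("extdata", "toy.vcf", package = "dgvar"))
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0) {
    return(empty_calls())
  }
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_id)) sample_id <- samples[1]
  if (!sample_id %in% samples) {
    abort(sprintf("sample '%s' not present in %s (has: %s)",
                  sample_id, path, paste(samples, collapse = ", ")))
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (any(!grepl("GT", fmt))) {
    abort(sprintf("missing GT genotype field at record line %d of %s",
                  which(!grepl("GT", fmt))[1], path))
  }
  if (any(!grepl("AD", fmt))) {
    abort(sprintf("missing AD allele-depth field at record line %d of %s",
                  which(!grepl("AD", fmt))[1], path))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample_id]
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample_id]

  rows <- purrr::pmap(
    list(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
         fix[, "ALT"], suppressWarnings(as.numeric(fix[, "QUAL"])), gt, ad),
    decompose_record
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_calls())
  out %>%
    mutate(sample_id = sample_id, .before = 1) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
}

empty_calls <- function() {
  tibble(sample_id = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), site_quality = double(),
         depth = integer(), alt_depth = integer(), genotype = character(),
         vaf = double())
}

# One VCF record -> zero or more single-alt rows.
decompose_record <- function(chrom, pos, ref, alt, qual, gt, ad) {
  if (is.na(gt) || gt %in% c("./.", ".|.", ".")) return(NULL)
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  ads <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
  depth <- sum(ads, na.rm = TRUE)
  gt_idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  gt_idx <- gt_idx[!is.na(gt_idx)]
  if (length(gt_idx) == 0 || all(gt_idx == 0)) return(NULL)
  carried <- sort(unique(gt_idx[gt_idx > 0]))
  purrr::map(carried, function(i) {
    n_copies <- sum(gt_idx == i)
    tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alts[i],
      site_quality = qual,
      depth = as.integer(depth),
      alt_depth = if (i + 1 <= length(ads)) ads[i + 1] else NA_integer_,
      genotype = if (n_copies >= 2) "hom_alt" else "het",
      vaf = if (depth > 0) ads[i + 1] / depth else NA_real_
    )
  }) %>% dplyr::bind_rows()
}

#' Write variant calls back to a single-sample VCF
#'
#' Emits one biallelic record per row with `GT:AD`, reconstructing AD as
#' `(depth - alt_depth, alt_depth)`. Reading the file back with
#' [read_vcf()] reproduces the input tibble.
#'
#' @param calls Variant-call tibble as produced by [read_vcf()].
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the tibble's value.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, path, sample_id = NULL) {
  assert_cols(calls, c("chrom", "pos", "ref", "alt", "site_quality",
                       "depth", "alt_depth", "genotype"), "calls")
  if (is.null(sample_id)) {
    sample_id <- if (nrow(calls) > 0 && "sample_id" %in% names(calls)) {
      calls$sample_id[1]
    } else "SAMPLE"
  }
  calls <- arrange(calls, .data$chrom, .data$pos, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  body <- if (nrow(calls) == 0) character() else {
    gt <- ifelse(calls$genotype == "hom_alt", "1/1", "0/1")
    ad <- paste(calls$depth - calls$alt_depth, calls$alt_depth, sep = ",")
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:AD\t%s:%s",
            calls$chrom, calls$pos, calls$ref, calls$alt,
            format_qual(calls$site_quality), gt, ad)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

format_qual <- function(q) {
  ifelse(is.na(q), ".",
         ifelse(q == round(q), sprintf("%d", as.integer(round(q))),
                sprintf("%.2f", q)))
}

#' Read a normalized somatic-caller VCF
#'
#' Parses one caller's tumor-normal VCF into a somatic-call tibble. The
#' file must carry `TUMOR` and `NORMAL` sample columns with GT:AD.
#' dbSNP membership is taken from an `rs`-prefixed ID and COSMIC
#' membership from a `COSMIC` tag in the ID or INFO field.
#'
#' @param path VCF path.
#' @param tumor_id Tumor sample identifier to stamp on every row.
#' @param caller One of `"mutect2"`, `"strelka"`, `"varscan"`,
#'   `"somaticsniper"`.
#' @return Tibble with `tumor_id`, `caller`, `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_depth`, `tumor_alt`, `tumor_vaf`, `normal_vaf`, `dbsnp`,
#'   `cosmic`.
#' @export
read_somatic_vcf <- function(path, tumor_id, caller) {
  caller <- match.arg(caller, .caller_levels)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  info <- tryCatch(vcfR::getINFO(vcf), error = function(e) rep("", nrow(fix)))
  if (is.null(dim(fix)) || nrow(fix) == 0) {
    return(tibble(tumor_id = character(), caller = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), tumor_depth = integer(),
                  tumor_alt = integer(), tumor_vaf = double(),
                  normal_vaf = double(), dbsnp = logical(), cosmic = logical()))
  }
  samples <- colnames(vcf@gt)[-1]
  for (s in c("TUMOR", "NORMAL")) {
    if (!s %in% samples) abort(sprintf("%s lacks a %s sample column", path, s))
  }
  parse_ad <- function(x) {
    m <- str_split(x, ",", simplify = TRUE)
    storage.mode(m) <- "integer"
    m
  }
  t_ad <- parse_ad(vcfR::extract.gt(vcf, "AD")[, "TUMOR"])
  n_ad <- parse_ad(vcfR::extract.gt(vcf, "AD")[, "NORMAL"])
  t_depth <- rowSums(t_ad, na.rm = TRUE)
  n_depth <- rowSums(n_ad, na.rm = TRUE)
  ids <- fix[, "ID"]
  tibble(
    tumor_id = tumor_id, caller = caller,
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    tumor_depth = as.integer(t_depth),
    tumor_alt = t_ad[, 2],
    tumor_vaf = ifelse(t_depth > 0, t_ad[, 2] / t_depth, 0),
    normal_vaf = ifelse(n_depth > 0, n_ad[, 2] / n_depth, 0),
    dbsnp = !is.na(ids) & str_starts(ids, "rs"),
    cosmic = (!is.na(ids) & str_detect(ids, "COSMIC")) |
      (!is.na(info) & str_detect(info, "COSMIC"))
  )
}
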