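# Multi-caller somatic consensus and post-consensus filtering.

.caller_priority <- c("mutect2", "strelka", "varscan", "somaticsniper")

#' Merge somatic calls from multiple callers into a consensus set
#'
#' Variants are keyed by (tumor, chrom, pos, ref, alt); only variants
#' reported by at least `min_callers` distinct callers are retained (the
#' indel callers are a subset of the SNV callers, so indels can reach
#' consensus from two callers). Duplicate records within one caller's
#' list are deduplicated with a warning. Numeric evidence fields are
#' taken from the highest-priority supporting caller (mutect2 > strelka
#' > varscan > somaticsniper); dbSNP/COSMIC flags are OR-ed across
#' callers.
#'
#' @param calls Tibble of per-caller somatic calls (rows from
#'   [read_somatic_vcf()] bound together; must have a `caller` column).
#' @param min_callers Consensus threshold (default 2).
#' @return Consensus tibble with a `callers` list-column and `n_callers`;
#'   attribute `filter_counts` records the variants removed by the
#'   consensus rule.
#' @export
merge_callers <- function(calls, min_callers = 2) {
  assert_cols(calls, c("tumor_id", "caller", "chrom", "pos", "ref", "alt"),
              "somatic calls")
  bad <- setdiff(unique(calls$caller), .caller_priority)
  if (length(bad) > 0) {
    abort(sprintf("unknown caller(s): %s", paste(bad, collapse = ", ")))
  }
  dup <- duplicated(calls[, c("tumor_id", "caller", "chrom", "pos",
                              "ref", "alt")])
  if (any(dup)) {
    warn(sprintf("%d duplicate record(s) within a caller list deduplicated",
                 sum(dup)))
    calls <- calls[!dup, , drop = FALSE]
  }
  calls <- calls %>%
    mutate(.prio = match(.data$caller, .caller_priority)) %>%
    arrange(.data$.prio)
  consensus <- calls %>%
    group_by(.data$tumor_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      callers = list(sort(unique(.data$caller))),
      n_callers = n_distinct(.data$caller),
      tumor_depth = first(.data$tumor_depth),
      tumor_alt = first(.data$tumor_alt),
      tumor_vaf = first(.data$tumor_vaf),
      normal_vaf = first(.data$normal_vaf),
      dbsnp = any(.data$dbsnp),
      cosmic = any(.data$cosmic),
      .groups = "drop"
    )
  keep <- consensus$n_callers >= min_callers
  res <- consensus[keep, , drop = FALSE]
  attr(res, "filter_counts") <- tibble(filter = "consensus",
                                       removed = sum(!keep))
  res
}

#' Apply post-consensus somatic filter criteria
#'
#' Retains consensus calls with (a) tumor depth >= 10 reads, (b) >= 3
#' reads supporting the alternate allele, (c) tumor VAF >= 5% and normal
#' VAF <= 1%, (d) not a dbSNP site unless also reported in COSMIC, and
#' (e) not on the technical-artifact blacklist. The criteria commute:
#' any application order yields the same retained set.
#'
#' @param calls Consensus tibble from [merge_callers()].
#' @param blacklist Character vector of artifact variant keys
#'   (`chrom:pos:ref:alt`), or `NULL`.
#' @param min_depth,min_alt,min_tumor_vaf,max_normal_vaf Thresholds as
#'   above.
#' @return Filtered tibble; attribute `filter_counts` records removals
#'   per criterion (first failing criterion in a-e order).
#' @export
apply_somatic_filters <- function(calls, blacklist = NULL,
                                  min_depth = 10, min_alt = 3,
                                  min_tumor_vaf = 0.05,
                                  max_normal_vaf = 0.01) {
  assert_cols(calls, c("tumor_depth", "tumor_alt", "tumor_vaf",
                       "normal_vaf", "dbsnp", "cosmic"), "consensus calls")
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  pass <- cbind(
    depth = calls$tumor_depth >= min_depth,
    alt_reads = calls$tumor_alt >= min_alt,
    vaf = calls$tumor_vaf >= min_tumor_vaf &
      calls$normal_vaf <= max_normal_vaf,
    dbsnp = !(calls$dbsnp & !calls$cosmic),
    artifact = if (is.null(blacklist)) rep(TRUE, nrow(calls)) else
      !key %in% blacklist
  )
  keep <- rowSums(!pass) == 0
  first_fail <- apply(pass, 1, function(p) {
    i <- which(!p)[1]
    if (is.na(i)) NA_character_ else colnames(pass)[i]
  })
  res <- calls[keep, , drop = FALSE]
  counts <- tibble(filter = colnames(pass)) %>%
    left_join(tibble(filter = first_fail[!keep]) %>%
                count(.data$filter, name = "removed"),
              by = "filter") %>%
    mutate(removed = replace_na(.data$removed, 0L))
  attr(res, "filter_counts") <- counts
  res
}
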