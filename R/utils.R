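# Shared vocabulary and small helpers used across the pipeline.

.effect_levels <- c("stop_gained", "frameshift", "synonymous", "missense",
                    "splice", "other")
.truncating_effects <- c("stop_gained", "frameshift")
.clinvar_levels <- c("pathogenic", "likely_pathogenic", "benign",
                     "likely_benign", "vus", "absent")
.genotype_levels <- c("het", "hom_alt", "hom_ref", "missing")
.caller_levels <- c("mutect2", "strelka", "varscan", "somaticsniper")

#' Build a variant key
#'
#' Joins chromosome, 1-based position, reference and alternate allele into
#' the `chrom:pos:ref:alt` string used as the join key throughout the
#' package (annotation lookup, exclusion lists, tumor observations).
#'
#' @param chrom,pos,ref,alt Vectors describing one alt allele per element.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

# Effect used for classification: canonical transcript wins when annotated.
effective_effect <- function(effect, canonical_effect) {
  dplyr::coalesce(canonical_effect, effect)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Deterministic sub-seed derivation so each component/patient has its own
# RNG stream; adding patients never perturbs earlier patients' draws.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}
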