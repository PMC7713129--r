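# Cohort QC profiles.

#' Create or fetch a germline filter profile
#'
#' A filter profile bundles the QC thresholds of the deleterious-variant
#' cascade. Two named profiles ship with the package:
#'
#' * `"wcm"` — site quality >= 50, depth >= 10 reads, VAF >= 0.35,
#'   SNV-cluster rule (>= 3 SNVs in a 10 bp window removed), population
#'   AF <= 0.01, cohort recurrence <= 0.05, ExAC inbreeding/VQSR pass
#'   required for truncating calls.
#' * `"spark"` — site quality >= 30, depth >= 8 reads, VAF >= 0.20, no
#'   cluster rule, otherwise as `"wcm"`.
#'
#' Thresholds keep the complement of the stated removal conditions, so
#' every boundary is inclusive on the retained side (a variant at exactly
#' quality 50 / depth 10 / VAF 0.35 / pop AF 0.01 / recurrence 0.05 is
#' retained under `"wcm"`).
#'
#' @param name `"wcm"`, `"spark"` or `"custom"`.
#' @param ... For `"custom"` (or to override a named profile): any of
#'   `min_site_quality`, `min_depth`, `min_vaf`, `snv_cluster_window`,
#'   `snv_cluster_min_count` (set to `Inf` to disable the cluster rule),
#'   `max_pop_af`, `cohort_recurrence_max`, `require_exac_qc`,
#'   `restrict_to_tsg` (when TRUE, ClinVar-pathogenic variants outside
#'   the TSG list are not retained).
#' @return A list of class `filter_profile`.
#' @examples
#' filter_profile("wcm")
#' filter_profile("spark", cohort_recurrence_max = 0.02)
#' @export
filter_profile <- function(name = c("wcm", "spark", "custom"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    min_site_quality = 50,
    min_depth = 10L,
    min_vaf = 0.35,
    snv_cluster_window = 10L,
    snv_cluster_min_count = 3,
    max_pop_af = 0.01,
    cohort_recurrence_max = 0.05,
    require_exac_qc = TRUE,
    restrict_to_tsg = FALSE
  )
  if (name == "spark") {
    base$min_site_quality <- 30
    base$min_depth <- 8L
    base$min_vaf <- 0.20
    base$snv_cluster_min_count <- Inf  # cluster rule not applied
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown filter profile field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  prof <- modifyList(base, dots)
  stopifnot(prof$snv_cluster_window >= 1,
            is.finite(prof$min_site_quality), is.finite(prof$min_depth),
            is.finite(prof$min_vaf), is.finite(prof$max_pop_af),
            is.finite(prof$cohort_recurrence_max))
  structure(prof, class = "filter_profile")
}

#' @export
print.filter_profile <- function(x, ...) {
  cat(sprintf("<filter_profile '%s'>\n", x$name))
  cat(sprintf("  quality >= %s, depth >= %s, VAF >= %s\n",
              x$min_site_quality, x$min_depth, x$min_vaf))
  if (is.finite(x$snv_cluster_min_count)) {
    cat(sprintf("  SNV cluster: >= %s SNVs in %s bp removed\n",
                x$snv_cluster_min_count, x$snv_cluster_window))
  } else {
    cat("  SNV cluster rule: disabled\n")
  }
  cat(sprintf("  pop AF <= %s, cohort recurrence <= %s, ExAC QC: %s\n",
              x$max_pop_af, x$cohort_recurrence_max, x$require_exac_qc))
  invisible(x)
}

as_filter_profile <- function(profile) {
  if (inherits(profile, "filter_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1) {
    return(filter_profile(profile))
  }
  abort("profile must be a filter_profile or a profile name")
}
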