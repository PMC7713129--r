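# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles (enumeration, exhaustive search) and
# share no code with the package implementations they check.

# Two-sided Fisher p by enumerating every table with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  probs <- vapply(xs, prob, numeric(1))
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct pmf summation.
oracle_hyper_upper <- function(k, n_pathway, n_universe, n_query) {
  xs <- k:min(n_pathway, n_query)
  if (length(xs) == 0 || k > min(n_pathway, n_query)) return(0)
  sum(vapply(xs, function(x) {
    choose(n_pathway, x) * choose(n_universe - n_pathway, n_query - x) /
      choose(n_universe, n_query)
  }, numeric(1)))
}

# Exact two-sided signed-rank p by brute-force sign-flip enumeration.
oracle_signflip_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sample KS p by enumerating every split of the pooled sample.
oracle_ks_perm <- function(x, y) {
  ks_stat <- function(x, y) {
    pooled <- sort(unique(c(x, y)))
    max(abs(vapply(pooled, function(t) mean(x <= t) - mean(y <= t),
                   numeric(1))))
  }
  d_obs <- ks_stat(x, y)
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  ds <- apply(idx, 2, function(i) ks_stat(pooled[i], pooled[-i]))
  list(statistic = d_obs, p_value = mean(ds >= d_obs - 1e-9))
}

# All-windows SNV-cluster scan: position i is flagged iff any window of
# `window` consecutive bp contains >= min_count SNV positions.
oracle_cluster_flags <- function(positions, window = 10, min_count = 3) {
  vapply(positions, function(p) {
    any(vapply(positions, function(start) {
      inside <- positions >= start & positions <= start + window - 1
      inside[match(p, positions)] && sum(inside) >= min_count
    }, logical(1)))
  }, logical(1))
}

# Naive per-variant re-evaluation of the whole deleterious-variant
# cascade, written as independent straight-line rules.
oracle_pdgv <- function(calls, ann, roles, profile, exclusion = character(),
                        cohort_size = NULL) {
  cohort_size <- cohort_size %||% length(unique(calls$patient_id))
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    a <- ann[ann$chrom == v$chrom & ann$pos == v$pos &
               ann$ref == v$ref & ann$alt == v$alt, ]
    ok <- TRUE
    if (is.na(v$site_quality) || v$site_quality < profile$min_site_quality) ok <- FALSE
    if (v$depth < profile$min_depth) ok <- FALSE
    if (is.na(v$vaf) || v$vaf < profile$min_vaf) ok <- FALSE
    # cluster rule
    if (is.finite(profile$snv_cluster_min_count) &&
        nchar(v$ref) == 1 && nchar(v$alt) == 1) {
      same <- calls[calls$patient_id == v$patient_id &
                      calls$chrom == v$chrom &
                      nchar(calls$ref) == 1 & nchar(calls$alt) == 1, ]
      for (start in same$pos) {
        inside <- same$pos >= start &
          same$pos <= start + profile$snv_cluster_window - 1
        if (v$pos >= start &&
            v$pos <= start + profile$snv_cluster_window - 1 &&
            sum(inside) >= profile$snv_cluster_min_count) ok <- FALSE
      }
    }
    pa <- if (nrow(a) == 0 || is.na(a$pop_af)) 0 else a$pop_af
    if (pa > profile$max_pop_af) ok <- FALSE
    # classification
    cls <- "neutral"
    if (nrow(a) == 1) {
      eff <- if (!is.na(a$canonical_effect)) a$canonical_effect else a$effect
      role <- roles$role[match(a$gene, roles$gene)]
      role <- if (is.na(role)) "none" else role
      benign <- a$clinvar_class %in% c("benign", "likely_benign")
      cvp <- a$clinvar_class %in% c("pathogenic", "likely_pathogenic") &&
        (is.na(a$clinvar_condition_is_cancer) || a$clinvar_condition_is_cancer)
      if (profile$restrict_to_tsg) cvp <- cvp && role == "TSG"
      tsg <- eff %in% c("stop_gained", "frameshift") && role == "TSG" &&
        (!profile$require_exac_qc || (a$inbreeding_pass && a$vqsr_pass))
      if (benign) cls <- "benign" else if (cvp || tsg) cls <- "deleterious"
    }
    if (cls != "deleterious") ok <- FALSE
    # recurrence
    carriers <- length(unique(calls$patient_id[
      calls$chrom == v$chrom & calls$pos == v$pos &
        calls$ref == v$ref & calls$alt == v$alt]))
    if (carriers / cohort_size > profile$cohort_recurrence_max) ok <- FALSE
    if (paste(v$chrom, v$pos, v$ref, v$alt, sep = ":") %in% exclusion) ok <- FALSE
    keep[i] <- ok
  }
  calls[keep, ]
}
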