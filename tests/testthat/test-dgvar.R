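# The germline filter cascade.

wcm <- filter_profile("wcm")

test_that("quality filters remove low-quality, low-depth and CHIP-range calls", {
  calls <- dplyr::bind_rows(
    make_call(pos = 1L, site_quality = 49.9, depth = 60L, alt_depth = 30L),
    make_call(pos = 2L, site_quality = 50, depth = 10L, alt_depth = 4L,
              vaf = 0.35),
    make_call(pos = 3L, site_quality = 99, depth = 60L, alt_depth = 20L)
  )
  out <- apply_quality_filters(calls, wcm)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE))
  expect_false(out$pass_quality[1])       # quality 49.9 < 50
  expect_true(all(out$pass_depth[2], out$pass_vaf[2]))  # boundary inclusive
  expect_false(out$pass_vaf[3])           # vaf 1/3 < 0.35: CHIP guard
  expect_equal(nrow(apply_quality_filters(calls[0, ], wcm)), 0)
})

test_that("spark profile relaxes thresholds to 30/8/0.20", {
  spark <- filter_profile("spark")
  call <- make_call(site_quality = 30, depth = 8L, alt_depth = 2L, vaf = 0.20)
  expect_true(apply_quality_filters(call, spark)$retained)
  expect_false(apply_quality_filters(call, wcm)$retained)
  expect_false(is.finite(spark$snv_cluster_min_count))
})

test_that("SNV cluster flagging matches the all-windows oracle", {
  mk <- function(pos) {
    dplyr::bind_rows(lapply(pos, function(p) make_call(pos = p)))
  }
  expect_equal(flag_alignment_clusters(mk(c(100, 104, 108))),
               rep(TRUE, 3))   # span 9 <= 10
  expect_equal(flag_alignment_clusters(mk(c(100, 105, 120))),
               rep(FALSE, 3))
  expect_equal(flag_alignment_clusters(mk(100)), FALSE)

  # indels never flagged
  calls <- mk(c(100, 104))
  calls <- dplyr::bind_rows(calls, make_call(pos = 108L, ref = "AT",
                                             alt = "A"))
  expect_equal(flag_alignment_clusters(calls), rep(FALSE, 3))

  # randomized positions against the oracle
  withr::with_seed(42, {
    for (i in 1:25) {
      pos <- sort(sample.int(60, sample(3:12, 1)))
      got <- flag_alignment_clusters(mk(pos))
      expect_equal(got, oracle_cluster_flags(pos), info = paste(pos, collapse = ","))
    }
  })

  # clusters are per patient, not pooled across the cohort
  two <- dplyr::bind_rows(make_call("P1", pos = 100L),
                          make_call("P2", pos = 104L),
                          make_call("P1", pos = 108L))
  expect_equal(flag_alignment_clusters(two), rep(FALSE, 3))
})

test_that("classification follows ClinVar and TSG-truncation rules", {
  roles <- basic_roles()
  base <- make_call()
  cls <- function(...) {
    ann <- make_ann(base, ...)
    classify_variants(annotate_calls(base, ann), roles, wcm)$classification
  }
  expect_equal(cls(gene = "TSG1", effect = "stop_gained"), "tsg_truncating")
  expect_equal(cls(gene = "GENE", effect = "missense",
                   clinvar_class = "likely_benign"), "clinvar_benign")
  # pathogenic for a non-cancer condition is excluded
  expect_equal(cls(gene = "GENE", effect = "missense",
                   clinvar_class = "pathogenic",
                   clinvar_condition_is_cancer = FALSE), "neutral")
  expect_equal(cls(gene = "GENE", effect = "missense",
                   clinvar_class = "pathogenic"), "clinvar_pathogenic")
  expect_equal(cls(gene = "TSG1", effect = "stop_gained",
                   clinvar_class = "pathogenic",
                   clinvar_condition_is_cancer = TRUE), "both")
  # ExAC QC failure blocks the truncation route
  expect_equal(cls(gene = "TSG1", effect = "stop_gained",
                   inbreeding_pass = FALSE), "neutral")
  # canonical transcript effect wins
  expect_equal(cls(gene = "TSG1", effect = "stop_gained",
                   canonical_effect = "missense"), "neutral")
  # frameshift outside the TSG list is not deleterious
  expect_equal(cls(gene = "OTHER", effect = "frameshift"), "neutral")
  # benign assertion overrides the truncation route
  expect_equal(cls(gene = "TSG1", effect = "stop_gained",
                   clinvar_class = "benign"), "clinvar_benign")
})

test_that("restrict_to_tsg limits the ClinVar route to listed genes", {
  prof <- filter_profile("wcm", restrict_to_tsg = TRUE)
  base <- make_call()
  ann <- make_ann(base, gene = "NOTLISTED", effect = "missense",
                  clinvar_class = "pathogenic")
  out <- classify_variants(annotate_calls(base, ann), basic_roles(), prof)
  expect_equal(out$classification, "neutral")
  out2 <- classify_variants(annotate_calls(base, ann), basic_roles(), wcm)
  expect_equal(out2$classification, "clinvar_pathogenic")
})

test_that("call_pdgvs applies the full cascade with a complete trace", {
  # clean pDGV carried by 1/40 patients
  carriers <- make_call(patient_id = sprintf("P%02d", 1:40), pos = 1:40 * 100L)
  target <- make_call("P01", pos = 5000L, site_quality = 99, depth = 60L,
                      alt_depth = 29L)
  calls <- dplyr::bind_rows(carriers, target)
  ann <- dplyr::bind_rows(
    make_ann(carriers, gene = "X", effect = "missense", pop_af = 0.2),
    make_ann(target, gene = "TSG1", effect = "stop_gained", pop_af = 5e-4))
  res <- call_pdgvs(calls, ann, basic_roles(), wcm)
  expect_s3_class(res, "pdgv_result")
  expect_equal(nrow(res$pdgvs), 1)
  expect_equal(res$pdgvs$gene, "TSG1")
  expect_equal(res$pdgvs$reason, "tsg_truncating")
  # trace: every excluded call has a failing filter recorded
  excl <- dplyr::filter(res$trace, !retained)
  expect_true(all(!is.na(excl$reason)))
  # conservation: input = retained + sum(per-reason removals)
  expect_equal(nrow(res$trace),
               nrow(res$pdgvs) + sum(filter_summary(res)$removed))
})

test_that("variants recurring in more than 5% of the cohort are artifacts", {
  # identical variant carried by 3/40 patients (7.5%)
  shared <- make_call(patient_id = c("P01", "P02", "P03"), pos = 777L)
  others <- make_call(patient_id = sprintf("P%02d", 4:40), pos = 4:40 * 10L)
  calls <- dplyr::bind_rows(shared, others)
  ann <- dplyr::bind_rows(
    make_ann(shared[1, ], gene = "TSG1", effect = "stop_gained"),
    make_ann(others, gene = "Y", effect = "missense", pop_af = 0.2))
  res <- call_pdgvs(calls, ann, basic_roles(), wcm, cohort_size = 40)
  expect_equal(nrow(res$pdgvs), 0)
  expect_equal(sum(res$trace$reason == "recurrence"), 3)
  # at 2/40 (5%, boundary) the same variant is retained
  res2 <- call_pdgvs(dplyr::bind_rows(shared[1:2, ], others), ann,
                     basic_roles(), wcm, cohort_size = 40)
  expect_equal(nrow(res2$pdgvs), 2)
})

test_that("exclusion list removes variants regardless of other filters", {
  call <- make_call()
  ann <- make_ann(call, gene = "TSG1", effect = "stop_gained")
  res <- call_pdgvs(call, ann, basic_roles(), wcm,
                    exclusion = "chr1:1000:A:T", cohort_size = 40)
  expect_equal(nrow(res$pdgvs), 0)
  expect_equal(res$trace$reason, "exclusion")
})

test_that("pDGV calling is order-independent and matches the naive oracle", {
  roles <- basic_roles()
  gen_cohort <- function() {
    n_pat <- sample(2:5, 1)
    calls <- dplyr::bind_rows(lapply(seq_len(n_pat), function(i) {
      n_var <- sample(5:20, 1)
      pos <- sample.int(500, n_var)
      depth <- sample(c(5L, 9L, 10L, 60L), n_var, replace = TRUE)
      make_call(patient_id = paste0("P", i), pos = pos,
                site_quality = sample(c(20, 49.9, 50, 99), n_var, TRUE),
                depth = depth,
                alt_depth = pmin(depth, sample(2:40, n_var, TRUE)))
    }))
    ann <- make_ann(
      calls,
      gene = sample(c("TSG1", "TSG2", "ONC1", "OTHER"),
                    nrow(dplyr::distinct(calls, chrom, pos, ref, alt)), TRUE),
      effect = sample(c("stop_gained", "frameshift", "missense",
                        "synonymous"), nrow(dplyr::distinct(calls, chrom, pos, ref, alt)), TRUE),
      clinvar_class = sample(c("absent", "pathogenic", "benign"),
                             nrow(dplyr::distinct(calls, chrom, pos, ref, alt)),
                             TRUE, prob = c(0.7, 0.2, 0.1)),
      pop_af = sample(c(0, 0.005, 0.01, 0.02, 0.2),
                      nrow(dplyr::distinct(calls, chrom, pos, ref, alt)), TRUE))
    list(calls = calls, ann = ann)
  }
  withr::with_seed(7, {
    for (rep in 1:10) {
      cx <- gen_cohort()
      res <- call_pdgvs(cx$calls, cx$ann, roles, wcm)
      naive <- oracle_pdgv(cx$calls, cx$ann, roles, wcm)
      got <- dplyr::arrange(res$pdgvs, patient_id, chrom, pos, alt)
      want <- dplyr::arrange(naive, patient_id, chrom, pos, alt)
      expect_equal(got$key,
                   variant_key(want$chrom, want$pos, want$ref, want$alt))
      expect_equal(got$patient_id, want$patient_id)
      # order independence
      shuf <- cx$calls[sample.int(nrow(cx$calls)), ]
      res2 <- call_pdgvs(shuf, cx$ann, roles, wcm)
      expect_equal(dplyr::arrange(res2$pdgvs, patient_id, chrom, pos, alt)$key,
                   got$key)
      # conservation holds on every generated cohort
      expect_equal(nrow(res$trace),
                   nrow(res$pdgvs) + sum(filter_summary(res)$removed))
    }
  })
})

test_that("tightening any single threshold never increases the pDGV count", {
  withr::with_seed(99, {
    n <- 60
    depth <- sample(5:120, n, TRUE)
    calls <- make_call(patient_id = sample(paste0("P", 1:6), n, TRUE),
                       pos = sample.int(5000, n),
                       site_quality = runif(n, 20, 200),
                       depth = depth,
                       alt_depth = pmin(depth, rbinom(n, depth, 0.45)))
    ukey <- dplyr::distinct(calls, chrom, pos, ref, alt)
    ann <- make_ann(calls,
                    gene = sample(c("TSG1", "TSG2", "OTHER"), nrow(ukey), TRUE),
                    effect = sample(c("stop_gained", "missense"), nrow(ukey), TRUE),
                    pop_af = runif(nrow(ukey), 0, 0.03))
    base_n <- nrow(call_pdgvs(calls, ann, basic_roles(), wcm)$pdgvs)
    tighter <- list(
      filter_profile("wcm", min_site_quality = 80),
      filter_profile("wcm", min_depth = 30),
      filter_profile("wcm", min_vaf = 0.45),
      filter_profile("wcm", max_pop_af = 0.005),
      filter_profile("wcm", cohort_recurrence_max = 0.01))
    for (prof in tighter) {
      expect_lte(nrow(call_pdgvs(calls, ann, basic_roles(), prof)$pdgvs),
                 base_n)
    }
  })
})

test_that("rare synonymous extraction mirrors the pDGV QC with AF < 1%", {
  calls <- dplyr::bind_rows(
    make_call(pos = 100L, site_quality = 80, depth = 40L, alt_depth = 20L),
    make_call(pos = 200L),
    make_call(pos = 300L))
  ann <- dplyr::bind_rows(
    make_ann(calls[1, ], gene = "A", effect = "synonymous", pop_af = 0.005),
    make_ann(calls[2, ], gene = "B", effect = "synonymous", pop_af = 0.02),
    make_ann(calls[3, ], gene = "C", effect = "missense", pop_af = 0.001))
  out <- extract_rare_synonymous(calls, ann, basic_roles(), wcm,
                                 cohort_size = 40)
  expect_equal(out$pos, 100L)
  # AF exactly 1% is excluded (strict <), unlike the deleterious cascade
  ann2 <- make_ann(calls[1, ], gene = "A", effect = "synonymous",
                   pop_af = 0.01)
  expect_equal(nrow(extract_rare_synonymous(calls[1, ], ann2, basic_roles(),
                                            wcm, cohort_size = 40)), 0)
  # same quality gates as the cascade
  lowq <- make_call(pos = 400L, site_quality = 30)
  ann3 <- make_ann(lowq, gene = "A", effect = "synonymous", pop_af = 0.001)
  expect_equal(nrow(extract_rare_synonymous(lowq, ann3, basic_roles(), wcm,
                                            cohort_size = 40)), 0)
  # conservation via recorded removals
  all_calls <- dplyr::bind_rows(calls, lowq)
  all_ann <- dplyr::bind_rows(ann, ann3)
  res <- extract_rare_synonymous(all_calls, all_ann, basic_roles(), wcm,
                                 cohort_size = 40)
  counts <- attr(res, "filter_counts")
  n_syn <- 3  # synonymous candidates among inputs
  expect_equal(n_syn, nrow(res) + sum(counts$removed))
})
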