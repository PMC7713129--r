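# The synthetic cohort generator and its planted truth.

test_that("the same seed reproduces a byte-identical bundle", {
  cfg <- sim_config(n_patients = 5, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_error(write_cohort(simulate_cohort(cfg), d1), "not empty")
})

test_that("adding patients never disturbs earlier patients' draws", {
  # artifact plants are cohort-level (their carrier set scales with the
  # cohort), so the stability property concerns the per-patient streams
  small <- simulate_cohort(sim_config(n_patients = 4, seed = 5,
                                      artifact_variant_count = 0))
  large <- simulate_cohort(sim_config(n_patients = 8, seed = 5,
                                      artifact_variant_count = 0))
  first4 <- dplyr::filter(large$calls,
                          patient_id %in% sprintf("P%03d", 1:4))
  expect_equal(first4, small$calls)
})

test_that("truth classes appear at the configured rates", {
  cfg <- sim_config(n_patients = 30, seed = 123)
  cohort <- simulate_cohort(cfg)
  counts <- dplyr::count(cohort$truth$variants, class)
  get <- function(cl) {
    n <- counts$n[counts$class == cl]
    if (length(n) == 0) 0L else n
  }
  expect_equal(get("common_snp"), 30 * cfg$common_snps_per_patient)
  expect_equal(get("rare_synonymous"), 30 * cfg$rare_synonymous_per_patient)
  expect_equal(get("background_truncating_nonTSG"),
               30 * cfg$nontsg_truncating_per_patient)
  # artifacts recur in > 5% of samples
  art <- dplyr::count(
    dplyr::filter(cohort$truth$variants, class == "artifact"), key)
  expect_true(all(art$n / 30 > 0.05))
  # Poisson-distributed plants: loose binomial band around the mean
  expect_gt(get("pdgv_tsg_truncating") + get("pdgv_clinvar"), 10)
  expect_lt(get("pdgv_tsg_truncating") + get("pdgv_clinvar"), 60)
})

test_that("planted deleterious variants satisfy the cascade preconditions", {
  cohort <- simulate_cohort(sim_config(n_patients = 10, seed = 31))
  pdgv_truth <- dplyr::filter(cohort$truth$variants, grepl("^pdgv", class))
  joined <- dplyr::inner_join(
    cohort$calls,
    dplyr::select(pdgv_truth, patient_id, chrom, pos, ref, alt),
    by = c("patient_id", "chrom", "pos", "ref", "alt"))
  expect_equal(nrow(joined), nrow(pdgv_truth))
  expect_true(all(joined$site_quality >= 50))
  expect_true(all(joined$depth >= 10))
  expect_true(all(joined$vaf >= 0.35))
  ann <- dplyr::semi_join(cohort$annotations, pdgv_truth,
                          by = c("chrom", "pos", "ref", "alt"))
  expect_true(all(is.na(ann$pop_af) | ann$pop_af < 0.01))
  # chip plants sit strictly inside the CHIP window
  chip <- dplyr::inner_join(
    cohort$calls,
    dplyr::filter(cohort$truth$variants, class == "chip_like"),
    by = c("patient_id", "chrom", "pos", "ref", "alt"))
  if (nrow(chip) > 0) {
    expect_true(all(chip$vaf > 0.0 & chip$vaf < 0.35))
  }
})

test_that("tumor read simulation follows the allele-fraction models", {
  # pure tumor, copy-neutral: every read carries the alt allele
  pure <- simulate_tumor_reads(1, TRUE, "copy_neutral", depth = rep(50L, 20),
                               seed = 1)
  expect_true(all(pure$alt_reads == 50))
  expect_equal(unique(pure$expected_vaf), 1)
  # purity 0.6, copy-neutral: expected raw VAF 0.8, corrected clamps to 1
  p6 <- simulate_tumor_reads(0.6, TRUE, "copy_neutral", depth = 10000L,
                             seed = 2)
  expect_equal(p6$expected_vaf, 0.8)
  expect_equal(p6$alt_reads / 10000, 0.8, tolerance = 0.02)
  expect_equal(corrected_vaf(p6$expected_vaf, 0.6), 1)
  # heterozygous null at any purity
  null <- simulate_tumor_reads(c(0.5, 0.9), FALSE, "copy_neutral",
                               depth = 10000L, seed = 3)
  expect_equal(unique(null$expected_vaf), 0.5)
  # hemizygous deletion of the reference allele at purity p: 1 / (2 - p)
  del <- simulate_tumor_reads(0.8, TRUE, "deletion", depth = 10000L,
                              seed = 4)
  expect_equal(del$expected_vaf, 1 / 1.2)
  expect_error(simulate_tumor_reads(0.5, TRUE, "inversion", 10L), "model")
  expect_error(simulate_tumor_reads(0, TRUE, "deletion", 10L), "purity")
})

test_that("caller outputs hit each caller at its sensitivity", {
  truth <- tibble::tibble(
    tumor_id = "T1", chrom = "chr1", pos = 1:1000, ref = "A", alt = "T",
    tumor_depth = 80L, tumor_alt = 30L, tumor_vaf = 30 / 80,
    normal_vaf = 0, dbsnp = FALSE, cosmic = FALSE)
  # perfect callers, no false positives: consensus recall 1
  perfect <- generate_caller_outputs(
    truth, c(mutect2 = 1, strelka = 1, varscan = 1, somaticsniper = 1),
    fp_rate = 0, seed = 5)
  cons <- merge_callers(perfect)
  expect_equal(nrow(cons), 1000)
  # a single-caller false positive is removed by the consensus rule
  fp <- dplyr::bind_rows(perfect,
                         make_somatic_call(caller = "mutect2", pos = 99999L))
  expect_false(99999L %in% merge_callers(fp)$pos)
  # determinism
  again <- generate_caller_outputs(
    truth, c(mutect2 = 1, strelka = 1, varscan = 1, somaticsniper = 1),
    fp_rate = 0, seed = 5)
  expect_identical(perfect, again)
  # indels only reach the indel-capable callers
  indel <- dplyr::mutate(truth[1:50, ], ref = "AT")
  out <- generate_caller_outputs(
    indel, c(mutect2 = 1, strelka = 1, varscan = 1, somaticsniper = 1),
    fp_rate = 0, seed = 6)
  expect_setequal(unique(out$caller), c("strelka", "varscan"))
})

test_that("a written bundle reads back into the same pipeline inputs", {
  cohort <- simulate_cohort(sim_config(n_patients = 4, seed = 9))
  d <- withr::local_tempdir()
  write_cohort(cohort, d)
  back <- read_cohort(d)
  expect_equal(back$calls, cohort$calls)
  expect_equal(back$manifest$tumors, cohort$manifest$tumors)
  expect_equal(nrow(back$annotations), nrow(cohort$annotations))
  expect_equal(back$pathways$genes, cohort$pathways$genes)
  expect_equal(
    dplyr::arrange(back$caller_calls, caller, tumor_id, chrom, pos, alt),
    dplyr::arrange(cohort$caller_calls, caller, tumor_id, chrom, pos, alt))
  expect_equal(dplyr::select(back$tumor_obs, -key) |>
                 dplyr::arrange(tumor_id, chrom, pos),
               dplyr::select(cohort$tumor_obs, -key) |>
                 dplyr::arrange(tumor_id, chrom, pos))
})
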