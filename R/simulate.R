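# Seeded synthetic cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the germline filter
# cascade works against: clean deleterious plants (ClinVar-pathogenic or
# TSG-truncating), common SNPs at population frequencies, platform
# artifacts recurring in > 5% of samples, CHIP-like sub-heterozygous
# variants, low-quality decoys each violating exactly one QC rule, rare
# synonymous variants, truncating variants in non-TSGs (the CADD/LOH
# background), plus serial tumors with planted copy-neutral or deletion
# LOH generating binomial read counts, and four somatic-caller outputs
# feeding the consensus merge. Every planted item is recorded in a truth
# table. All draws come from per-patient, per-component RNG streams, so
# the same seed always produces the same cohort and adding patients does
# not disturb existing ones.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline is calibrated for:
#' a 40-patient whole-exome cohort at 85x mean coverage, about one
#' deleterious germline plant per patient, tumor purity 0.5-0.95, an LOH
#' probability of 0.5 per (variant, tumor) with a 0.25 boost in
#' metastases, and four somatic callers at 0.9 sensitivity.
#'
#' @param n_patients Number of patients.
#' @param pdgv_rate Expected deleterious plants per patient (Poisson).
#' @param common_snps_per_patient,rare_synonymous_per_patient,
#'   nontsg_truncating_per_patient,low_quality_per_patient Planted
#'   background counts per patient.
#' @param chip_variant_rate Expected CHIP-like plants per patient.
#' @param artifact_variant_count Number of platform-artifact variants,
#'   each planted in >5% of samples.
#' @param common_snp_af_range Population AF range of common SNPs.
#' @param depth_mean,depth_size Negative-binomial read-depth model
#'   (mean 85x).
#' @param purity_range Tumor purity range (uniform).
#' @param low_purity_fraction Fraction of tumors drawn below the LOH QC
#'   purity cutoff (exercises the QC filter).
#' @param met_fraction Fraction of patients with a metastatic second
#'   tumor.
#' @param loh_probability LOH probability per (deleterious variant,
#'   tumor).
#' @param met_loh_boost Additional LOH probability in metastases.
#' @param loh_copy_neutral_prob Probability an LOH event is copy-neutral
#'   (vs hemizygous deletion).
#' @param background_loh_probability LOH probability at non-TSG control
#'   loci.
#' @param somatic_per_tumor True somatic variants per tumor.
#' @param cn_loss_rate Probability a tumor carries a copy-number loss of
#'   one of its patient's deleterious-variant genes.
#' @param gsi_plant_rate Probability that a tumor of a pDGV carrier
#'   receives a somatic truncating TSG hit inside a pathway shared with
#'   one of the patient's deleterious germline genes (plants in-trans
#'   interactions).
#' @param caller_sensitivities Named per-caller detection probabilities.
#' @param caller_fp_rate Expected private false positives per caller per
#'   tumor.
#' @param n_genes Size of the synthetic gene model.
#' @param n_pathways Number of pathway gene sets.
#' @param seed Integer seed (required).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 40,
                       pdgv_rate = 1,
                       common_snps_per_patient = 8,
                       rare_synonymous_per_patient = 8,
                       nontsg_truncating_per_patient = 25,
                       low_quality_per_patient = 3,
                       chip_variant_rate = 0.5,
                       artifact_variant_count = 2,
                       common_snp_af_range = c(0.015, 0.5),
                       depth_mean = 85,
                       depth_size = 25,
                       purity_range = c(0.5, 0.95),
                       low_purity_fraction = 0.1,
                       met_fraction = 0.5,
                       loh_probability = 0.5,
                       met_loh_boost = 0.25,
                       loh_copy_neutral_prob = 0.5,
                       background_loh_probability = 0.05,
                       somatic_per_tumor = 8,
                       cn_loss_rate = 0.2,
                       gsi_plant_rate = 0.4,
                       caller_sensitivities = c(mutect2 = 0.9, strelka = 0.9,
                                                varscan = 0.9,
                                                somaticsniper = 0.9),
                       caller_fp_rate = 2,
                       n_genes = 400,
                       n_pathways = 25,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is required")
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1,
            all(cfg$caller_sensitivities >= 0 & cfg$caller_sensitivities <= 1),
            cfg$loh_probability >= 0, cfg$loh_probability <= 1)
  structure(cfg, class = "sim_config")
}

# ---- gene model -----------------------------------------------------------

sim_gene_model <- function(cfg) {
  n <- cfg$n_genes
  gene <- sprintf("G%04d", seq_len(n))
  role <- rep("none", n)
  role[seq_len(floor(n * 0.3))] <- "TSG"
  role[floor(n * 0.3) + seq_len(floor(n * 0.15))] <- "oncogene"
  chrom <- paste0("chr", (seq_len(n) - 1) %% 22 + 1)
  start <- 1e5 * (((seq_len(n) - 1) %/% 22) + 1)
  genes <- tibble(gene = gene, role = role, chrom = chrom, start = start)
  pathways <- withr::with_seed(derive_seed(cfg$seed, "pathways"), {
    tibble(
      pathway_id = sprintf("PW%03d", seq_len(cfg$n_pathways)),
      name = sprintf("pathway_%03d", seq_len(cfg$n_pathways)),
      genes = purrr::map(seq_len(cfg$n_pathways), function(i) {
        sort(sample(gene, sample(8:20, 1)))
      })
    )
  })
  list(genes = genes, pathways = pathways)
}

# position index k within a gene -> genomic position; the 50 bp grid
# guarantees ordinary plants never trip the 10 bp cluster rule, and the
# per-patient 1 kb offset keeps loci of different patients from
# colliding at identical keys (shared loci are planted explicitly:
# artifact and somatic slots live above offset 95 kb)
gene_pos <- function(genes, gene, k, pidx = 0L) {
  i <- match(gene, genes$gene)
  genes$start[i] + 1000L * as.integer(pidx) + 50L * as.integer(k)
}

rdepth <- function(n, cfg, min_depth = 20L) {
  d <- rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_size)
  pmax(d, min_depth)
}

# het alt count conditioned on VAF >= floor (rejection by redraw)
rhet_alt <- function(depth, floor_vaf = 0.35) {
  alt <- rbinom(length(depth), depth, 0.5)
  for (it in 1:50) {
    low <- alt / depth < floor_vaf
    if (!any(low)) break
    alt[low] <- rbinom(sum(low), depth[low], 0.5)
  }
  alt[alt / depth < floor_vaf] <- ceiling(depth[alt / depth < floor_vaf] * 0.5)
  alt
}

rsnv_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- purrr::map_chr(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1))
  tibble(ref = ref, alt = alt)
}

# ---- germline layer -------------------------------------------------------

# builds calls + annotations + truth rows for one patient
sim_patient_germline <- function(cfg, model, patient_id, pidx, artifacts) {
  genes <- model$genes
  tsg <- genes$gene[genes$role == "TSG"]
  non_tsg <- genes$gene[genes$role != "TSG"]
  rows <- list()
  k_counter <- new.env()
  next_k <- function(g) {
    k <- (get0(g, envir = k_counter, ifnotfound = 0L)) + 1L
    assign(g, k, envir = k_counter)
    k
  }
  add <- function(class, gene, effect, n = 1, clinvar = "absent",
                  cancer_cond = NA, pop_af = NA_real_, quality = NULL,
                  depth = NULL, alt = NULL, genotype = "het",
                  inbreeding = TRUE, vqsr = TRUE, cadd = NA_real_,
                  indel = FALSE, pos = NULL, canonical = NA_character_) {
    depth <- depth %||% rdepth(n, cfg)
    alt_d <- alt %||% rhet_alt(depth)
    al <- rsnv_alleles(n)
    # frameshifts are single-base deletions (never SNV-cluster flagged)
    fs <- rep_len(effect, n) == "frameshift"
    al$alt[fs] <- al$ref[fs]
    al$ref[fs] <- paste0(al$ref[fs], "T")
    g_i <- match(gene, genes$gene)
    pos <- pos %||% gene_pos(genes, gene,
                             purrr::map_int(gene, function(g) next_k(g)),
                             pidx)
    tibble(
      patient_id = patient_id, class = class, gene = gene,
      chrom = genes$chrom[g_i], pos = as.integer(pos),
      ref = al$ref, alt = al$alt,
      site_quality = quality %||% round(runif(n, 60, 1500), 1),
      depth = as.integer(depth), alt_depth = as.integer(alt_d),
      genotype = genotype,
      effect = effect, canonical_effect = canonical,
      clinvar_class = clinvar, clinvar_condition_is_cancer = cancer_cond,
      pop_af = pop_af, inbreeding_pass = inbreeding, vqsr_pass = vqsr,
      cadd_phred = cadd, dbsnp = !is.na(pop_af) & pop_af > 0.001,
      cosmic = FALSE
    )
  }

  # deleterious plants: TSG-truncating (70%) or ClinVar-pathogenic (30%)
  n_pdgv <- rpois(1, cfg$pdgv_rate)
  if (n_pdgv > 0) {
    for (i in seq_len(n_pdgv)) {
      if (runif(1) < 0.7) {
        g <- sample(tsg, 1)
        rows[[length(rows) + 1]] <- add(
          "pdgv_tsg_truncating", g,
          effect = sample(c("stop_gained", "frameshift"), 1),
          pop_af = runif(1, 0, 0.009),
          cadd = pmax(20, rnorm(1, 35, 5)),
          genotype = if (runif(1) < 0.1) "hom_alt" else "het")
      } else {
        g <- sample(tsg, 1)  # cancer-gene ClinVar assertions
        rows[[length(rows) + 1]] <- add(
          "pdgv_clinvar", g,
          effect = sample(c("missense", "stop_gained"), 1),
          clinvar = sample(c("pathogenic", "likely_pathogenic"), 1),
          cancer_cond = sample(c(TRUE, NA), 1),
          pop_af = runif(1, 0, 0.009),
          cadd = pmax(20, rnorm(1, 33, 5)))
      }
    }
  }
  hom_fix <- function(df) {
    hom <- df$genotype == "hom_alt"
    df$alt_depth[hom] <- df$depth[hom]
    df
  }

  # common SNPs: removed by the population-frequency rule alone
  n_c <- cfg$common_snps_per_patient
  if (n_c > 0) {
    rows[[length(rows) + 1]] <- add(
      "common_snp", sample(genes$gene, n_c, replace = FALSE),
      effect = sample(c("synonymous", "missense"), n_c, replace = TRUE),
      n = n_c,
      pop_af = runif(n_c, cfg$common_snp_af_range[1],
                     cfg$common_snp_af_range[2]))
  }

  # rare synonymous: the burden-test denominator
  n_s <- cfg$rare_synonymous_per_patient
  if (n_s > 0) {
    rows[[length(rows) + 1]] <- add(
      "rare_synonymous", sample(genes$gene, n_s, replace = FALSE),
      effect = "synonymous", n = n_s,
      pop_af = runif(n_s, 0, 0.009))
  }

  # truncating variants in non-TSGs: CADD and LOH background
  n_b <- cfg$nontsg_truncating_per_patient
  if (n_b > 0) {
    rows[[length(rows) + 1]] <- add(
      "background_truncating_nonTSG",
      sample(non_tsg, n_b, replace = FALSE),
      effect = sample(c("stop_gained", "frameshift"), n_b, replace = TRUE),
      n = n_b, pop_af = runif(n_b, 0, 0.009),
      cadd = pmax(0, rnorm(n_b, 15, 5)))
  }

  # CHIP-like: sub-heterozygous VAF is the only disqualifying attribute
  n_chip <- rpois(1, cfg$chip_variant_rate)
  if (n_chip > 0) {
    depth <- rdepth(n_chip, cfg)
    alt <- pmax(1L, rbinom(n_chip, depth, runif(n_chip, 0.08, 0.30)))
    alt <- pmin(alt, ceiling(depth * 0.30))
    rows[[length(rows) + 1]] <- add(
      "chip_like", sample(tsg, n_chip, replace = FALSE),
      effect = "stop_gained", n = n_chip,
      pop_af = runif(n_chip, 0, 0.009), depth = depth, alt = alt,
      cadd = pmax(20, rnorm(n_chip, 35, 5)))
  }

  # low-quality decoys: each violates exactly one QC rule
  n_lq <- cfg$low_quality_per_patient
  if (n_lq > 0) {
    modes <- rep(c("quality", "depth", "cluster"), length.out = n_lq)
    for (m in modes) {
      g <- sample(tsg, 1)
      if (m == "quality") {
        rows[[length(rows) + 1]] <- add(
          "low_quality", g, effect = "stop_gained",
          pop_af = runif(1, 0, 0.009), quality = round(runif(1, 10, 45), 1))
      } else if (m == "depth") {
        d <- sample(4:8, 1)
        rows[[length(rows) + 1]] <- add(
          "low_quality", g, effect = "stop_gained",
          pop_af = runif(1, 0, 0.009), depth = d,
          alt = as.integer(ceiling(d * 0.5)))
      } else {
        base <- gene_pos(model$genes, g, next_k(g), pidx) + 7L
        rows[[length(rows) + 1]] <- add(
          "low_quality", rep(g, 3), effect = "stop_gained", n = 3,
          pop_af = runif(3, 0, 0.009), pos = base + c(0L, 4L, 8L))
      }
    }
  }

  out <- hom_fix(bind_rows(rows))
  # artifact plants recur at identical loci across selected patients
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    mine <- artifacts[purrr::map_lgl(artifacts$patients,
                                     function(p) patient_id %in% p), ]
    if (nrow(mine) > 0) {
      depth <- rdepth(nrow(mine), cfg)
      art <- tibble(
        patient_id = patient_id, class = "artifact", gene = mine$gene,
        chrom = mine$chrom, pos = mine$pos, ref = mine$ref, alt = mine$alt,
        site_quality = round(runif(nrow(mine), 60, 1500), 1),
        depth = as.integer(depth),
        alt_depth = as.integer(rhet_alt(depth)),
        genotype = "het", effect = "stop_gained",
        canonical_effect = NA_character_, clinvar_class = "absent",
        clinvar_condition_is_cancer = NA,
        pop_af = mine$pop_af, inbreeding_pass = TRUE, vqsr_pass = TRUE,
        cadd_phred = NA_real_, dbsnp = FALSE, cosmic = FALSE
      )
      out <- bind_rows(out, art)
    }
  }
  mutate(out, vaf = ifelse(.data$depth > 0,
                           .data$alt_depth / .data$depth, NA_real_))
}

sim_artifacts <- function(cfg, model) {
  if (cfg$artifact_variant_count == 0) {
    return(tibble(gene = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), pop_af = double(),
                  patients = list()))
  }
  tsg <- model$genes$gene[model$genes$role == "TSG"]
  n_aff <- max(3L, ceiling(0.075 * cfg$n_patients))
  g <- sample(tsg, cfg$artifact_variant_count)
  al <- rsnv_alleles(cfg$artifact_variant_count)
  tibble(
    gene = g,
    chrom = model$genes$chrom[match(g, model$genes$gene)],
    pos = model$genes$start[match(g, model$genes$gene)] + 95000L +
      seq_along(g),
    ref = al$ref, alt = al$alt,
    pop_af = runif(cfg$artifact_variant_count, 0, 0.009),
    patients = purrr::map(seq_along(g), function(i) {
      sample(sprintf("P%03d", seq_len(cfg$n_patients)), n_aff)
    })
  )
}

# ---- tumor layer ----------------------------------------------------------

#' Simulate tumor read counts at a germline heterozygous locus
#'
#' Draws `(ref_reads, alt_reads)` from a binomial allele model at the
#' given sequencing depth. Without LOH the expected alt fraction is 0.5.
#' Under copy-neutral LOH at purity p, tumor cells carry two alt copies
#' of two, admixed normal cells one of two: expected alt fraction
#' `(1 + p) / 2`. Under hemizygous deletion of the reference allele,
#' tumor cells carry one alt copy of one remaining: expected alt
#' fraction `1 / (2 - p)`.
#'
#' @param purity Tumor purity in (0, 1].
#' @param loh Logical: is the locus under LOH in this tumor?
#' @param model `"copy_neutral"` or `"deletion"` (vectorized with `loh`).
#' @param depth Integer read depth(s).
#' @param seed Optional integer seed.
#' @return Tibble with `ref_reads`, `alt_reads`, `expected_vaf`.
#' @export
simulate_tumor_reads <- function(purity, loh, model = "copy_neutral",
                                 depth, seed = NULL) {
  if (any(is.na(purity) | purity <= 0 | purity > 1)) {
    abort("purity must be in (0, 1]")
  }
  bad <- setdiff(unique(model), c("copy_neutral", "deletion"))
  if (length(bad) > 0) abort(sprintf("invalid LOH model: %s", bad[1]))
  n <- max(length(purity), length(loh), length(depth), length(model))
  purity <- rep_len(purity, n); loh <- rep_len(loh, n)
  depth <- rep_len(depth, n); model <- rep_len(model, n)
  q <- ifelse(!loh, 0.5,
              ifelse(model == "copy_neutral", (1 + purity) / 2,
                     1 / (2 - purity)))
  draw <- function() {
    alt <- rbinom(n, depth, q)
    tibble(ref_reads = as.integer(depth - alt), alt_reads = as.integer(alt),
           expected_vaf = q)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

sim_tumors <- function(cfg, patient_ids) {
  n <- length(patient_ids)
  has_met <- runif(n) < cfg$met_fraction
  prim <- tibble(tumor_id = paste0(patient_ids, "_T1"),
                 patient_id = patient_ids, site = "primary")
  mets <- tibble(tumor_id = paste0(patient_ids[has_met], "_T2"),
                 patient_id = patient_ids[has_met], site = "metastatic")
  tumors <- bind_rows(prim, mets)
  low <- runif(nrow(tumors)) < cfg$low_purity_fraction
  tumors$purity <- ifelse(
    low, round(runif(nrow(tumors), 0.2, 0.45), 2),
    round(runif(nrow(tumors), cfg$purity_range[1], cfg$purity_range[2]), 2))
  tumors$purity_source <- sample(c("clonet", "pathology"), nrow(tumors),
                                 replace = TRUE, prob = c(0.8, 0.2))
  arrange(tumors, .data$patient_id, .data$tumor_id)
}

sim_tumor_observations <- function(cfg, tumors, germline) {
  # loci observed in every tumor: deleterious plants + non-TSG controls
  loci <- germline %>%
    filter(.data$class %in% c("pdgv_tsg_truncating", "pdgv_clinvar",
                              "background_truncating_nonTSG"),
           .data$genotype == "het") %>%
    select("patient_id", "class", "gene", "chrom", "pos", "ref", "alt")
  obs <- list()
  loh_truth <- list()
  for (pid in unique(tumors$patient_id)) {
    p_loci <- loci[loci$patient_id == pid, , drop = FALSE]
    if (nrow(p_loci) == 0) next
    p_tumors <- tumors[tumors$patient_id == pid, , drop = FALSE]
    withr::with_seed(derive_seed(cfg$seed, "tumor", pid), {
      is_dgv <- p_loci$class != "background_truncating_nonTSG"
      base_p <- ifelse(is_dgv, cfg$loh_probability,
                       cfg$background_loh_probability)
      loh_primary <- runif(nrow(p_loci)) < base_p
      model <- sample(c("copy_neutral", "deletion"), nrow(p_loci),
                      replace = TRUE,
                      prob = c(cfg$loh_copy_neutral_prob,
                               1 - cfg$loh_copy_neutral_prob))
      for (ti in seq_len(nrow(p_tumors))) {
        tum <- p_tumors[ti, ]
        loh <- if (tum$site == "metastatic") {
          loh_primary | (runif(nrow(p_loci)) < cfg$met_loh_boost & is_dgv)
        } else loh_primary
        depth <- rdepth(nrow(p_loci), cfg, min_depth = 12L)
        reads <- simulate_tumor_reads(tum$purity, loh, model, depth)
        obs[[length(obs) + 1]] <- tibble(
          tumor_id = tum$tumor_id, chrom = p_loci$chrom, pos = p_loci$pos,
          ref = p_loci$ref, alt = p_loci$alt,
          ref_reads = reads$ref_reads, alt_reads = reads$alt_reads)
        loh_truth[[length(loh_truth) + 1]] <- tibble(
          patient_id = pid, tumor_id = tum$tumor_id, site = tum$site,
          purity = tum$purity,
          chrom = p_loci$chrom, pos = p_loci$pos, ref = p_loci$ref,
          alt = p_loci$alt, class = p_loci$class, gene = p_loci$gene,
          loh = loh, model = ifelse(loh, model, NA_character_),
          expected_raw_vaf = reads$expected_vaf)
      }
    })
  }
  list(observations = bind_rows(obs), loh_truth = bind_rows(loh_truth))
}

# ---- somatic layer --------------------------------------------------------

sim_somatic <- function(cfg, model, tumors, germline) {
  pathway_tbl <- model$pathways
  genes <- model$genes
  tsg <- genes$gene[genes$role == "TSG"]
  onc <- genes$gene[genes$role == "oncogene"]
  truth <- list()
  ann <- list()
  cn <- list()
  for (ti in seq_len(nrow(tumors))) {
    tum <- tumors[ti, ]
    withr::with_seed(derive_seed(cfg$seed, "somatic", tum$tumor_id), {
      n <- cfg$somatic_per_tumor
      kind <- sample(c("tsg_truncating", "oncogene_missense", "passenger"),
                     n, replace = TRUE, prob = c(0.35, 0.35, 0.3))
      g <- character(n)
      g[kind == "tsg_truncating"] <- sample(tsg, sum(kind == "tsg_truncating"))
      g[kind == "oncogene_missense"] <- sample(onc, sum(kind == "oncogene_missense"))
      g[kind == "passenger"] <- sample(genes$gene[genes$role == "none"],
                                       sum(kind == "passenger"))
      al <- rsnv_alleles(n)
      depth <- rdepth(n, cfg, min_depth = 15L)
      vaf_target <- runif(n, 0.12, 0.45)
      alt <- pmax(4L, rbinom(n, depth, vaf_target))
      eff <- ifelse(kind == "tsg_truncating", "stop_gained",
                    ifelse(kind == "oncogene_missense", "missense",
                           "missense"))
      # plant an in-trans interaction: somatic truncating hit in a TSG
      # sharing a pathway with one of the patient's deleterious genes
      dgv_genes_all <- germline$gene[germline$patient_id == tum$patient_id &
                                       grepl("^pdgv", germline$class)]
      if (length(dgv_genes_all) > 0 && runif(1) < cfg$gsi_plant_rate) {
        holds_dgv <- purrr::map_lgl(pathway_tbl$genes,
                                    function(gs) any(dgv_genes_all %in% gs))
        cand <- pathway_tbl$genes[holds_dgv]
        cand_tsg <- setdiff(intersect(unlist(cand), tsg), dgv_genes_all)
        cand_tsg <- setdiff(cand_tsg, g)
        if (length(cand_tsg) > 0) {
          slot <- which(kind == "passenger")[1]
          if (!is.na(slot)) {
            kind[slot] <- "tsg_truncating"
            g[slot] <- sample(cand_tsg, 1)
            eff <- NULL  # recomputed below
          }
        }
      }
      eff <- ifelse(kind == "tsg_truncating", "stop_gained", "missense")
      dbsnp <- runif(n) < 0.1
      cosmic <- dbsnp & runif(n) < 0.5  # half the dbSNP sites rescue via COSMIC
      pos <- genes$start[match(g, genes$gene)] + 97000L + seq_len(n)
      tvaf <- alt / depth
      talt <- as.integer(alt)
      tdepth <- as.integer(depth)
      truth[[length(truth) + 1]] <- tibble(
        tumor_id = tum$tumor_id, patient_id = tum$patient_id,
        gene = g, kind = kind,
        chrom = genes$chrom[match(g, genes$gene)], pos = pos,
        ref = al$ref, alt = al$alt,
        tumor_depth = tdepth, tumor_alt = talt,
        tumor_vaf = tvaf, normal_vaf = 0,
        dbsnp = dbsnp, cosmic = cosmic, effect = eff)
      # copy-number loss of one of the patient's deleterious TSG genes
      dgv_genes <- germline$gene[germline$patient_id == tum$patient_id &
                                   germline$class == "pdgv_tsg_truncating"]
      if (length(dgv_genes) > 0 && runif(1) < cfg$cn_loss_rate) {
        cn[[length(cn) + 1]] <- tibble(tumor_id = tum$tumor_id,
                                       gene = sample(dgv_genes, 1),
                                       direction = "loss")
      }
    })
  }
  truth <- bind_rows(truth)
  list(truth = truth,
       cn_events = if (length(cn)) bind_rows(cn) else
         tibble(tumor_id = character(), gene = character(),
                direction = character()))
}

#' Scatter true somatic variants across caller outputs
#'
#' Each true variant is detected by each caller independently with that
#' caller's sensitivity (indels only by strelka/varscan); private false
#' positives are injected per caller at a Poisson rate. Single-caller
#' false positives are what the two-caller consensus rule removes.
#'
#' @param somatic_truth Tibble of true somatic variants (as produced by
#'   the cohort simulator; needs locus, read-count and flag columns plus
#'   `tumor_id`).
#' @param caller_sensitivities Named vector over the four callers.
#' @param fp_rate Expected private false positives per caller per tumor.
#' @param seed Integer seed.
#' @return Per-caller call tibble suitable for [merge_callers()].
#' @export
generate_caller_outputs <- function(somatic_truth,
                                    caller_sensitivities = c(
                                      mutect2 = 0.9, strelka = 0.9,
                                      varscan = 0.9, somaticsniper = 0.9),
                                    fp_rate = 0, seed = 1L) {
  stopifnot(all(caller_sensitivities >= 0 & caller_sensitivities <= 1))
  callers <- names(caller_sensitivities)
  stopifnot(all(callers %in% .caller_levels))
  withr::with_seed(seed, {
    out <- purrr::map_dfr(callers, function(cl) {
      sens <- caller_sensitivities[[cl]]
      eligible <- somatic_truth
      is_indel <- nchar(eligible$ref) != 1 | nchar(eligible$alt) != 1
      if (!cl %in% c("strelka", "varscan")) {
        eligible <- eligible[!is_indel, , drop = FALSE]
      }
      hit <- runif(nrow(eligible)) < sens
      det <- eligible[hit, , drop = FALSE] %>%
        transmute(.data$tumor_id, caller = cl, .data$chrom, .data$pos,
                  .data$ref, .data$alt, .data$tumor_depth,
                  .data$tumor_alt, .data$tumor_vaf, .data$normal_vaf,
                  .data$dbsnp, .data$cosmic)
      fps <- purrr::map_dfr(unique(somatic_truth$tumor_id), function(tid) {
        n_fp <- rpois(1, fp_rate)
        if (n_fp == 0) return(NULL)
        al <- rsnv_alleles(n_fp)
        depth <- pmax(20L, rnbinom(n_fp, mu = 85, size = 25))
        alt <- pmax(3L, rbinom(n_fp, depth, 0.1))
        tvaf <- alt / depth
        talt <- as.integer(alt)
        tibble(tumor_id = tid, caller = cl, chrom = "chrFP",
               pos = sample.int(1e6, n_fp),
               ref = al$ref, alt = al$alt,
               tumor_depth = as.integer(depth), tumor_alt = talt,
               tumor_vaf = tvaf, normal_vaf = 0,
               dbsnp = FALSE, cosmic = FALSE)
      })
      bind_rows(det, fps)
    })
    out
  })
}

# ---- top level ------------------------------------------------------------

#' Generate a complete synthetic cohort with planted truth
#'
#' Produces every input the pipeline consumes — per-patient germline
#' calls, the annotation table, gene roles, pathway gene sets, the
#' cohort manifest with tumor purities, forced tumor read counts at
#' germline loci, per-caller somatic calls and gene-level copy-number
#' events — together with truth tables recording each planted variant's
#' class and each (variant, tumor) LOH state. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `dgv_cohort` with elements `calls`,
#'   `annotations`, `roles`, `pathways`, `manifest`, `tumor_obs`,
#'   `caller_calls`, `cn_events`, `truth` (list: `variants`, `loh`,
#'   `somatic`) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 4, seed = 7))
#' dplyr::count(cohort$truth$variants, class)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  model <- withr::with_seed(derive_seed(cfg$seed, "genes"),
                            sim_gene_model(cfg))
  patient_ids <- sprintf("P%03d", seq_len(cfg$n_patients))
  artifacts <- withr::with_seed(derive_seed(cfg$seed, "artifacts"),
                                sim_artifacts(cfg, model))
  germline <- purrr::imap_dfr(patient_ids, function(pid, i) {
    withr::with_seed(derive_seed(cfg$seed, "germline", pid),
                     sim_patient_germline(cfg, model, pid, i, artifacts))
  })
  tumors <- withr::with_seed(derive_seed(cfg$seed, "tumors"),
                             sim_tumors(cfg, patient_ids))
  tum_layer <- sim_tumor_observations(cfg, tumors, germline)
  som <- sim_somatic(cfg, model, tumors, germline)
  caller_calls <- generate_caller_outputs(
    som$truth, cfg$caller_sensitivities, cfg$caller_fp_rate,
    seed = derive_seed(cfg$seed, "callers"))

  calls <- germline %>%
    select("patient_id", "chrom", "pos", "ref", "alt", "site_quality",
           "depth", "alt_depth", "genotype", "vaf") %>%
    arrange(.data$patient_id, .data$chrom, .data$pos, .data$alt)
  annotations <- bind_rows(
    germline %>%
      select("chrom", "pos", "ref", "alt", "gene", "effect",
             "canonical_effect", "clinvar_class",
             "clinvar_condition_is_cancer", "pop_af", "inbreeding_pass",
             "vqsr_pass", "cadd_phred", "dbsnp", "cosmic"),
    som$truth %>%
      transmute(.data$chrom, .data$pos, .data$ref, .data$alt, .data$gene,
                effect = .data$effect, canonical_effect = NA_character_,
                clinvar_class = "absent",
                clinvar_condition_is_cancer = NA, pop_af = NA_real_,
                inbreeding_pass = TRUE, vqsr_pass = TRUE,
                cadd_phred = NA_real_, dbsnp = .data$dbsnp,
                cosmic = .data$cosmic)
  ) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
             .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$pos, .data$alt) %>%
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  manifest <- structure(
    list(patients = tibble(patient_id = patient_ids,
                           ethnicity = withr::with_seed(
                             derive_seed(cfg$seed, "ethnicity"),
                             sample(c("EUR", "AJ"), cfg$n_patients,
                                    replace = TRUE, prob = c(0.85, 0.15))),
                           germline_sample = paste0(patient_ids, "_N")),
         tumors = tumors,
         filter_profile = "wcm"),
    class = "cohort_manifest")
  truth_variants <- germline %>%
    select("patient_id", "class", "gene", "chrom", "pos", "ref", "alt",
           "genotype") %>%
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  structure(list(
    calls = calls, annotations = annotations,
    roles = model$genes %>% filter(.data$role != "none") %>%
      select("gene", "role"),
    pathways = model$pathways, manifest = manifest,
    tumor_obs = mutate(tum_layer$observations,
                       key = variant_key(.data$chrom, .data$pos,
                                         .data$ref, .data$alt)),
    caller_calls = caller_calls,
    cn_events = som$cn_events,
    truth = list(variants = truth_variants, loh = tum_layer$loh_truth,
                 somatic = som$truth),
    config = cfg
  ), class = "dgv_cohort")
}

#' @export
print.dgv_cohort <- function(x, ...) {
  cat(sprintf("<dgv_cohort: %d patients, %d germline calls, %d tumors, seed %d>\n",
              nrow(x$manifest$patients), nrow(x$calls),
              nrow(x$manifest$tumors), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes per-patient germline VCFs (`germline/<patient>.vcf`), the
#' annotation table, gene roles, pathway GMT, YAML manifest, tumor
#' observation TSV, per-caller somatic VCFs
#' (`somatic/<tumor>__<caller>.vcf`), copy-number events, an empty
#' exclusion list and the truth tables. All files are plain text and
#' byte-stable for a given seed.
#'
#' @param cohort A `dgv_cohort`.
#' @param dir Output directory; must not already contain files.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (dir.exists(dir) && length(list.files(dir)) > 0) {
    abort(sprintf("output directory %s is not empty", dir))
  }
  dir.create(file.path(dir, "germline"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "somatic"), showWarnings = FALSE)
  for (pid in cohort$manifest$patients$patient_id) {
    p_calls <- cohort$calls %>%
      filter(.data$patient_id == pid) %>%
      rename(sample_id = "patient_id")
    write_vcf(p_calls, file.path(dir, "germline", paste0(pid, ".vcf")),
              sample_id = pid)
  }
  readr::write_tsv(select(cohort$annotations, -"key"),
                   file.path(dir, "annotations.tsv"))
  readr::write_tsv(cohort$roles, file.path(dir, "gene_roles.tsv"))
  write_gene_sets(cohort$pathways, file.path(dir, "pathways.gmt"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.yaml"))
  readr::write_tsv(select(cohort$tumor_obs, -"key"),
                   file.path(dir, "tumor_observations.tsv"))
  readr::write_tsv(cohort$cn_events, file.path(dir, "cn_events.tsv"))
  readr::write_tsv(tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()),
                   file.path(dir, "exclusion.tsv"))
  for (tid in unique(cohort$caller_calls$tumor_id)) {
    for (cl in unique(cohort$caller_calls$caller)) {
      cc <- cohort$caller_calls %>%
        filter(.data$tumor_id == tid, .data$caller == cl) %>%
        arrange(.data$chrom, .data$pos, .data$alt)
      write_somatic_vcf(cc, file.path(dir, "somatic",
                                      paste0(tid, "__", cl, ".vcf")))
    }
  }
  readr::write_tsv(cohort$truth$variants, file.path(dir, "truth_variants.tsv"))
  readr::write_tsv(cohort$truth$loh, file.path(dir, "truth_loh.tsv"))
  readr::write_tsv(select(cohort$truth$somatic, -"effect"),
                   file.path(dir, "truth_somatic.tsv"))
  invisible(dir)
}

# minimal normalized two-sample somatic VCF writer
write_somatic_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL")
  body <- if (nrow(calls) == 0) character() else {
    id <- ifelse(calls$dbsnp,
                 paste0("rs", abs(calls$pos * 13 + 7) %% 1000000),
                 ".")
    id <- ifelse(calls$cosmic, paste0(id, ";COSMIC"), id)
    t_ad <- paste(calls$tumor_depth - calls$tumor_alt, calls$tumor_alt,
                  sep = ",")
    n_depth <- 60L
    n_alt <- as.integer(round(calls$normal_vaf * n_depth))
    n_ad <- paste(n_depth - n_alt, n_alt, sep = ",")
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT:AD\t0/1:%s\t0/0:%s",
            calls$chrom, calls$pos, id, calls$ref, calls$alt, t_ad, n_ad)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a synthetic cohort bundle from disk
#'
#' Inverse of [write_cohort()]: loads every pipeline input (and the
#' truth tables when present) back into a `dgv_cohort`-shaped list.
#'
#' @param dir Bundle directory.
#' @return List with the same elements as [simulate_cohort()] output
#'   (minus `config`).
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.yaml"))
  calls <- purrr::map_dfr(manifest$patients$patient_id, function(pid) {
    read_vcf(file.path(dir, "germline", paste0(pid, ".vcf")), pid) %>%
      rename(patient_id = "sample_id")
  })
  som_files <- list.files(file.path(dir, "somatic"), full.names = TRUE)
  caller_calls <- purrr::map_dfr(som_files, function(f) {
    stem <- sub("\\.vcf$", "", basename(f))
    parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
    read_somatic_vcf(f, tumor_id = parts[1], caller = parts[2])
  })
  truth <- NULL
  if (file.exists(file.path(dir, "truth_variants.tsv"))) {
    truth <- list(
      variants = readr::read_tsv(file.path(dir, "truth_variants.tsv"),
                                 show_col_types = FALSE),
      loh = readr::read_tsv(file.path(dir, "truth_loh.tsv"),
                            show_col_types = FALSE),
      somatic = readr::read_tsv(file.path(dir, "truth_somatic.tsv"),
                                show_col_types = FALSE))
  }
  list(
    calls = calls,
    annotations = read_annotation_table(file.path(dir, "annotations.tsv")),
    roles = read_gene_roles(file.path(dir, "gene_roles.tsv")),
    pathways = read_gene_sets(file.path(dir, "pathways.gmt")),
    manifest = manifest,
    tumor_obs = read_tumor_observations(
      file.path(dir, "tumor_observations.tsv")),
    caller_calls = caller_calls,
    cn_events = read_cn_events(file.path(dir, "cn_events.tsv")),
    exclusion = read_exclusion_list(file.path(dir, "exclusion.tsv")),
    truth = truth
  )
}
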