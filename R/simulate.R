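#' Configure a synthetic multi-omics study
#'
#' Defines the cohort shapes, planted effects and noise model for
#' [generate_study()]. Defaults emulate a TNBC-style TCGA cohort: 55
#' expression tumor/normal pairs, 53 copy-number pairs, 32/27 and 23/47
#' tumor/normal beta-value groups on two methylation platforms, 53/103 miRNA
#' groups, and a 54-sample case MAF inside a 992-sample background cohort.
#'
#' Planted genes occupy deterministic index blocks so the ground truth is
#' explicit: a triple-evidence block (expression + copy gain +
#' hypomethylation, the genes expected to reach Level 3), two double blocks
#' (GE+CN, GE+ME), a GE-only block, CN-only and ME-only blocks, a block of
#' miRNA-target genes wired to the planted downregulated miRNAs, and a block
#' of mutation-enriched genes. Default planted effects: 4-fold expression,
#' linear copy 3 vs 2 (1.5-fold), beta depression 0.2, 4-fold miRNA
#' downregulation, qualifying-mutation rates 0.4 (cases) vs 0.05 (rest of the
#' background). Non-planted genes carry a realistic passenger
#' qualifying-mutation rate of 0.0015 per gene per sample.
#'
#' @param seed Integer seed (mandatory); all randomness flows from it through
#'   one child stream per modality.
#' @param n_genes Number of genes in the toy genome.
#' @param genes_per_chrom,gene_length,gene_spacing Toy genome layout (bases).
#' @param n_pairs_expression,n_pairs_cnv Tumor/normal pair counts.
#' @param me_a_tumor,me_a_normal,me_b_tumor,me_b_normal Methylation group sizes.
#' @param mirna_tumor,mirna_normal miRNA group sizes.
#' @param n_case_maf,n_background_maf Mutation cohort sizes; the case samples
#'   are the first `n_case_maf` samples of the background cohort.
#' @param n_mirnas Number of miRNAs.
#' @param n_planted_triple,n_planted_ge_cn,n_planted_ge_me,n_planted_ge_only
#'   GE-containing planted blocks.
#' @param n_planted_cn_only,n_planted_me_only Single-modality blocks.
#' @param n_planted_mirna,targets_per_mirna Downregulated miRNAs and targets
#'   each (their targets form the planted MR gene block).
#' @param n_decoy_mirnas,decoy_targets_per_mirna Non-planted miRNAs wired to
#'   null genes, so the target map contains decoys.
#' @param n_planted_gm Mutation-enriched gene block size.
#' @param ge_fold,cn_copy,me_delta,mirna_fold Planted effect sizes.
#' @param gm_case_rate,gm_background_rate Qualifying-mutation rates for
#'   planted GM genes in case vs non-case background samples.
#' @param passenger_rate Qualifying-mutation rate for non-planted genes
#'   (default 0.0015, roughly 30 qualifying calls per exome spread over a
#'   20,000-gene genome).
#' @param silent_rate Extra rate of Silent calls (all genes, all samples).
#' @param expr_baseline_log2_mean,expr_baseline_log2_sd Per-gene baseline
#'   log2 expression distribution.
#' @param expr_noise_sd,mirna_noise_sd Within-group log2 noise.
#' @param cn_seg_sd Gaussian noise on segment log2(copy/2) values.
#' @param beta_precision Beta-distribution precision (a + b) for beta values.
#' @param probe_sd SD of per-probe offsets around the gene beta mean.
#' @param probes_min,probes_max Probes per gene per platform.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 2000L,
                              genes_per_chrom = 200L,
                              gene_length = 10000L,
                              gene_spacing = 10000L,
                              n_pairs_expression = 55L,
                              n_pairs_cnv = 53L,
                              me_a_tumor = 32L, me_a_normal = 27L,
                              me_b_tumor = 23L, me_b_normal = 47L,
                              mirna_tumor = 53L, mirna_normal = 103L,
                              n_case_maf = 54L, n_background_maf = 992L,
                              n_mirnas = 300L,
                              n_planted_triple = 25L,
                              n_planted_ge_cn = 25L,
                              n_planted_ge_me = 25L,
                              n_planted_ge_only = 25L,
                              n_planted_cn_only = 50L,
                              n_planted_me_only = 50L,
                              n_planted_mirna = 10L,
                              targets_per_mirna = 10L,
                              n_decoy_mirnas = 50L,
                              decoy_targets_per_mirna = 10L,
                              n_planted_gm = 100L,
                              ge_fold = 4,
                              cn_copy = 3,
                              me_delta = 0.2,
                              mirna_fold = 4,
                              gm_case_rate = 0.4,
                              gm_background_rate = 0.05,
                              passenger_rate = 0.0015,
                              silent_rate = 0.001,
                              expr_baseline_log2_mean = 8,
                              expr_baseline_log2_sd = 2,
                              expr_noise_sd = 0.5,
                              mirna_noise_sd = 0.5,
                              cn_seg_sd = 0.2,
                              beta_precision = 30,
                              probe_sd = 0.02,
                              probes_min = 2L,
                              probes_max = 5L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort_argument("`seed` is mandatory")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  n_mr_genes <- cfg$n_planted_mirna * cfg$targets_per_mirna
  n_planted <- cfg$n_planted_triple + cfg$n_planted_ge_cn + cfg$n_planted_ge_me +
    cfg$n_planted_ge_only + cfg$n_planted_cn_only + cfg$n_planted_me_only +
    n_mr_genes + cfg$n_planted_gm
  if (n_planted > cfg$n_genes) {
    abort_argument(sprintf("planted blocks (%d genes) exceed n_genes (%d)",
                           n_planted, cfg$n_genes))
  }
  if (cfg$n_case_maf > cfg$n_background_maf) {
    abort_argument("case cohort cannot exceed the background cohort")
  }
  positive <- c("ge_fold", "mirna_fold")
  for (f in positive) {
    if (cfg[[f]] <= 1) abort_argument(sprintf("`%s` must exceed 1", f))
  }
  if (cfg$cn_copy <= 2) abort_argument("`cn_copy` must exceed the neutral copy 2")
  for (f in c("gm_case_rate", "gm_background_rate", "passenger_rate",
              "silent_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort_argument(sprintf("`%s` must lie in [0, 1]", f))
    }
  }
  if (cfg$me_delta <= 0 || cfg$me_delta >= 0.3) {
    abort_argument("`me_delta` must lie in (0, 0.3) so beta means stay in range")
  }
  if (cfg$n_planted_mirna + cfg$n_decoy_mirnas > cfg$n_mirnas) {
    abort_argument("planted plus decoy miRNAs exceed n_mirnas")
  }
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @details `null_simulation_config()` presets a small all-null study (no
#'   planted effects, 500 genes, reduced cohorts) for calibration runs.
#' @param ... Overrides passed through to [simulation_config()].
#' @export
null_simulation_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_genes = 500L, genes_per_chrom = 100L,
                   n_pairs_expression = 20L, n_pairs_cnv = 20L,
                   me_a_tumor = 12L, me_a_normal = 12L,
                   me_b_tumor = 10L, me_b_normal = 16L,
                   mirna_tumor = 20L, mirna_normal = 40L,
                   n_case_maf = 20L, n_background_maf = 100L,
                   n_mirnas = 60L,
                   n_planted_triple = 0L, n_planted_ge_cn = 0L,
                   n_planted_ge_me = 0L, n_planted_ge_only = 0L,
                   n_planted_cn_only = 0L, n_planted_me_only = 0L,
                   n_planted_mirna = 0L, n_decoy_mirnas = 10L,
                   n_planted_gm = 0L)
  do.call(simulation_config, modifyList(defaults, list(...)))
}

# Deterministic planted-gene index blocks. Returns a list of integer vectors.
planted_blocks <- function(cfg) {
  cursor <- 0L
  take <- function(n) {
    out <- if (n > 0) seq.int(cursor + 1L, cursor + n) else integer(0)
    cursor <<- cursor + n
    out
  }
  list(triple = take(cfg$n_planted_triple),
       ge_cn = take(cfg$n_planted_ge_cn),
       ge_me = take(cfg$n_planted_ge_me),
       ge_only = take(cfg$n_planted_ge_only),
       cn_only = take(cfg$n_planted_cn_only),
       me_only = take(cfg$n_planted_me_only),
       mr = take(cfg$n_planted_mirna * cfg$targets_per_mirna),
       gm = take(cfg$n_planted_gm))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sim_expression_like <- function(gene_ids, log2_fold_tumor, n_pairs, prefix,
                                baseline_mean, baseline_sd, noise_sd) {
  n <- length(gene_ids)
  base <- rnorm(n, baseline_mean, baseline_sd)
  tum <- 2^(base + log2_fold_tumor +
              matrix(rnorm(n * n_pairs, 0, noise_sd), n, n_pairs))
  nor <- 2^(base + matrix(rnorm(n * n_pairs, 0, noise_sd), n, n_pairs))
  t_ids <- sprintf("%s_T%03d", prefix, seq_len(n_pairs))
  n_ids <- sprintf("%s_N%03d", prefix, seq_len(n_pairs))
  mat <- cbind(tum, nor)
  dimnames(mat) <- list(gene_ids, c(t_ids, n_ids))
  design <- sample_design(c(t_ids, n_ids),
                          rep(c("tumor", "normal"), each = n_pairs),
                          pair_id = rep(sprintf("%s_P%03d", prefix,
                                                seq_len(n_pairs)), 2))
  list(mat = mat, design = design)
}

sim_beta_platform <- function(gene_ids, delta_tumor, n_tumor, n_normal,
                              platform, gene_mu, cfg) {
  n_probes_per_gene <- sample(seq.int(cfg$probes_min, cfg$probes_max),
                              length(gene_ids), replace = TRUE)
  gene_idx <- rep(seq_along(gene_ids), n_probes_per_gene)
  n_probes <- length(gene_idx)
  probe_ids <- sprintf("cg%s%06d", platform, seq_len(n_probes))
  probe_mu <- clamp(gene_mu[gene_idx] + rnorm(n_probes, 0, cfg$probe_sd),
                    0.02, 0.98)
  tumor_mu <- clamp(probe_mu - delta_tumor[gene_idx], 0.01, 0.99)
  phi <- cfg$beta_precision
  draw <- function(mu, n_samples) {
    matrix(rbeta(length(mu) * n_samples, rep(mu, n_samples) * phi,
                 rep(1 - mu, n_samples) * phi),
           nrow = length(mu), ncol = n_samples)
  }
  tum <- draw(tumor_mu, n_tumor)
  nor <- draw(probe_mu, n_normal)
  t_ids <- sprintf("ME%s_T%03d", platform, seq_len(n_tumor))
  n_ids <- sprintf("ME%s_N%03d", platform, seq_len(n_normal))
  mat <- cbind(tum, nor)
  dimnames(mat) <- list(probe_ids, c(t_ids, n_ids))
  list(beta = omics_matrix(mat, "beta"),
       probe_map = tibble(probe_id = probe_ids, gene_id = gene_ids[gene_idx]),
       design = sample_design(c(t_ids, n_ids),
                              rep(c("tumor", "normal"), c(n_tumor, n_normal))))
}

#' Generate a seeded synthetic multi-omics study
#'
#' Produces every pipeline input plus a ground-truth table. Expression and
#' miRNA values are log-normal (per-feature baseline log2 mean ~
#' Normal(`expr_baseline_log2_mean`, `expr_baseline_log2_sd`^2), Gaussian
#' within-group log2 noise; tumor means multiplied by the planted fold).
#' Copy-number segments cover each gene of a toy genome, neutral (linear copy
#' 2) everywhere except planted copy-gain genes in tumor samples (linear copy
#' `cn_copy`), emitted as log2(copy/2) SEG records with Gaussian segment
#' noise. Beta values are Beta-distributed around planted gene means with 2-5
#' probes per gene per platform. The target map wires each planted
#' downregulated miRNA to its block of target genes, plus decoy miRNAs wired
#' to null genes. Mutation calls are Bernoulli per gene and sample at the
#' planted case/background rates (passenger rate elsewhere), with additional
#' Silent calls that the default screen filter removes.
#'
#' Identical configs (including seed) give identical studies; each modality
#' draws from its own child seed so modalities are independently
#' reproducible.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_study` with the pipeline inputs
#'   (`gene_model`, `expression`, `design_expression`, `segments`,
#'   `design_cnv`, `beta_a`/`probe_map_a`/`design_me_a`, likewise `_b`,
#'   `mirna`, `design_mirna`, `target_map`, `maf`, `case_samples`,
#'   `background_samples`) and `truth` (tibbles `features` and `genes`, the
#'   latter with the expected nominal level of every planted gene).
#' @export
generate_study <- function(config) {
  cfg <- config
  if (!inherits(cfg, "simulation_config")) {
    abort_argument("`config` must be a simulation_config")
  }
  set.seed(cfg$seed)
  child <- sample.int(.Machine$integer.max - 1L, 7L)
  blocks <- planted_blocks(cfg)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))

  # toy genome
  chrom_of <- (seq_len(cfg$n_genes) - 1L) %/% cfg$genes_per_chrom + 1L
  idx_on <- (seq_len(cfg$n_genes) - 1L) %% cfg$genes_per_chrom
  starts <- idx_on * (cfg$gene_length + cfg$gene_spacing) + 1L
  gene_model <- tibble(gene_id = gene_ids,
                       chrom = sprintf("chr%d", chrom_of),
                       start = as.integer(starts),
                       end = as.integer(starts + cfg$gene_length - 1L))

  ge_genes <- c(blocks$triple, blocks$ge_cn, blocks$ge_me, blocks$ge_only)
  cn_genes <- c(blocks$triple, blocks$ge_cn, blocks$cn_only)
  me_genes <- c(blocks$triple, blocks$ge_me, blocks$me_only)
  mr_genes <- blocks$mr
  gm_genes <- blocks$gm

  # expression
  set.seed(child[1])
  lfc <- numeric(cfg$n_genes)
  lfc[ge_genes] <- log2(cfg$ge_fold)
  expr <- sim_expression_like(gene_ids, lfc, cfg$n_pairs_expression, "GE",
                              cfg$expr_baseline_log2_mean,
                              cfg$expr_baseline_log2_sd, cfg$expr_noise_sd)

  # copy number: one segment per gene per sample
  set.seed(child[2])
  np <- cfg$n_pairs_cnv
  t_ids <- sprintf("CN_T%03d", seq_len(np))
  n_ids <- sprintf("CN_N%03d", seq_len(np))
  copy_gene <- rep(2, cfg$n_genes)
  copy_gene[cn_genes] <- cfg$cn_copy
  seg_one <- function(sample_ids, copies) {
    k <- length(sample_ids)
    tibble(sample_id = rep(sample_ids, each = cfg$n_genes),
           chrom = rep(gene_model$chrom, k),
           start = rep(gene_model$start, k),
           end = rep(gene_model$end, k),
           seg_value = rep(log2(copies / 2), k) +
             rnorm(k * cfg$n_genes, 0, cfg$cn_seg_sd))
  }
  segments <- bind_rows(seg_one(t_ids, copy_gene),
                        seg_one(n_ids, rep(2, cfg$n_genes)))
  design_cnv <- sample_design(c(t_ids, n_ids),
                              rep(c("tumor", "normal"), each = np),
                              pair_id = rep(sprintf("CN_P%03d", seq_len(np)), 2))

  # methylation (two platforms, shared gene means, independent probes)
  set.seed(child[3])
  gene_mu <- runif(cfg$n_genes, 0.3, 0.7)
  delta <- numeric(cfg$n_genes)
  delta[me_genes] <- cfg$me_delta
  plat_a <- sim_beta_platform(gene_ids, delta, cfg$me_a_tumor, cfg$me_a_normal,
                              "A", gene_mu, cfg)
  set.seed(child[4])
  plat_b <- sim_beta_platform(gene_ids, delta, cfg$me_b_tumor, cfg$me_b_normal,
                              "B", gene_mu, cfg)

  # miRNA
  set.seed(child[5])
  mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  lfc_mir <- numeric(cfg$n_mirnas)
  planted_mirnas <- seq_len(cfg$n_planted_mirna)
  lfc_mir[planted_mirnas] <- -log2(cfg$mirna_fold)  # down in tumors
  n_mir <- max(cfg$mirna_tumor, cfg$mirna_normal)
  base <- rnorm(cfg$n_mirnas, cfg$expr_baseline_log2_mean,
                cfg$expr_baseline_log2_sd)
  tum <- 2^(base + lfc_mir + matrix(rnorm(cfg$n_mirnas * cfg$mirna_tumor, 0,
                                          cfg$mirna_noise_sd),
                                    cfg$n_mirnas, cfg$mirna_tumor))
  nor <- 2^(base + matrix(rnorm(cfg$n_mirnas * cfg$mirna_normal, 0,
                                cfg$mirna_noise_sd),
                          cfg$n_mirnas, cfg$mirna_normal))
  mt_ids <- sprintf("MR_T%03d", seq_len(cfg$mirna_tumor))
  mn_ids <- sprintf("MR_N%03d", seq_len(cfg$mirna_normal))
  mir_mat <- cbind(tum, nor)
  dimnames(mir_mat) <- list(mirna_ids, c(mt_ids, mn_ids))
  design_mirna <- sample_design(c(mt_ids, mn_ids),
                                rep(c("tumor", "normal"),
                                    c(cfg$mirna_tumor, cfg$mirna_normal)))

  # target map: planted miRNAs -> MR gene block; decoy miRNAs -> null genes
  set.seed(child[6])
  tm_rows <- list()
  if (cfg$n_planted_mirna > 0) {
    tm_rows$planted <- tibble(
      mirna_id = rep(mirna_ids[planted_mirnas], each = cfg$targets_per_mirna),
      gene_id = gene_ids[mr_genes])
  }
  null_pool <- setdiff(seq_len(cfg$n_genes), unlist(blocks))
  if (cfg$n_decoy_mirnas > 0 && length(null_pool) > 0) {
    decoys <- sample(setdiff(seq_len(cfg$n_mirnas), planted_mirnas),
                     cfg$n_decoy_mirnas)
    tm_rows$decoy <- tibble(
      mirna_id = rep(mirna_ids[decoys], each = cfg$decoy_targets_per_mirna),
      gene_id = gene_ids[sample(null_pool,
                                cfg$n_decoy_mirnas * cfg$decoy_targets_per_mirna,
                                replace = TRUE)])
  }
  target_map <- distinct(bind_rows(tm_rows))

  # mutations
  set.seed(child[7])
  bg_ids <- sprintf("BC%04d", seq_len(cfg$n_background_maf))
  case_ids <- bg_ids[seq_len(cfg$n_case_maf)]
  rate <- matrix(cfg$passenger_rate, cfg$n_genes, cfg$n_background_maf)
  if (length(gm_genes) > 0) {
    rate[gm_genes, ] <- cfg$gm_background_rate
    rate[gm_genes, seq_len(cfg$n_case_maf)] <- cfg$gm_case_rate
  }
  qual <- matrix(rbinom(length(rate), 1L, rate), cfg$n_genes)
  silent <- matrix(rbinom(length(rate), 1L, cfg$silent_rate), cfg$n_genes)
  qi <- which(qual == 1L, arr.ind = TRUE)
  si <- which(silent == 1L, arr.ind = TRUE)
  classes <- sample(c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del"),
                    nrow(qi), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  maf <- bind_rows(
    tibble(gene_id = gene_ids[qi[, 1]], sample_id = bg_ids[qi[, 2]],
           variant_classification = classes),
    tibble(gene_id = gene_ids[si[, 1]], sample_id = bg_ids[si[, 2]],
           variant_classification = "Silent"))
  maf <- arrange(maf, .data$gene_id, .data$sample_id,
                 .data$variant_classification)

  # ground truth
  feats <- bind_rows(
    tibble(modality = "GE", feature_id = gene_ids[ge_genes],
           effect = cfg$ge_fold),
    tibble(modality = "CN", feature_id = gene_ids[cn_genes],
           effect = cfg$cn_copy / 2),
    tibble(modality = "ME", feature_id = gene_ids[me_genes],
           effect = cfg$me_delta),
    tibble(modality = "MR", feature_id = mirna_ids[planted_mirnas],
           effect = cfg$mirna_fold),
    tibble(modality = "MR_target", feature_id = gene_ids[mr_genes],
           effect = cfg$mirna_fold),
    tibble(modality = "GM", feature_id = gene_ids[gm_genes],
           effect = cfg$gm_case_rate))
  planted_any <- sort(unique(c(ge_genes, cn_genes, me_genes, mr_genes, gm_genes)))
  truth_genes <- tibble(
    gene_id = gene_ids[planted_any],
    GE = planted_any %in% ge_genes,
    CN = planted_any %in% cn_genes,
    ME = planted_any %in% me_genes,
    MR = planted_any %in% mr_genes,
    GM = planted_any %in% gm_genes)
  other <- rowSums(as.matrix(truth_genes[, c("CN", "ME", "MR", "GM")]))
  truth_genes$expected_level <- ifelse(truth_genes$GE, 1L + other, NA_integer_)

  structure(list(
    gene_model = gene_model,
    expression = omics_matrix(expr$mat, "expression"),
    design_expression = expr$design,
    segments = segments,
    design_cnv = design_cnv,
    beta_a = plat_a$beta, probe_map_a = plat_a$probe_map,
    design_me_a = plat_a$design,
    beta_b = plat_b$beta, probe_map_b = plat_b$probe_map,
    design_me_b = plat_b$design,
    mirna = omics_matrix(mir_mat, "mirna"),
    design_mirna = design_mirna,
    target_map = target_map,
    maf = maf,
    case_samples = case_ids,
    background_samples = bg_ids,
    truth = list(features = feats, genes = truth_genes),
    config = cfg), class = "synthetic_study")
}

study_files <- c(
  gene_model = "gene_model.bed",
  expression = "expression.tsv",
  design_expression = "design_expression.tsv",
  segments = "segments.seg",
  design_cnv = "design_cnv.tsv",
  beta_a = "meth_platform_a.tsv",
  probe_map_a = "probe_map_a.tsv",
  design_me_a = "design_meth_a.tsv",
  beta_b = "meth_platform_b.tsv",
  probe_map_b = "probe_map_b.tsv",
  design_me_b = "design_meth_b.tsv",
  mirna = "mirna.tsv",
  design_mirna = "design_mirna.tsv",
  target_map = "target_map.tsv",
  maf = "mutations.maf",
  maf_cohort = "maf_cohort.tsv")

#' Write a synthetic study to a directory
#'
#' Emits every pipeline input (SEG, MAF, BED, TSV matrices, designs, target
#' map), the truth tables, and a `MANIFEST.tsv` enumerating the files. Errors
#' if the directory already contains a study unless `overwrite = TRUE`.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @param overwrite Allow writing into a directory holding a previous study.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, overwrite = FALSE) {
  if (dir.exists(dir) && file.exists(file.path(dir, "MANIFEST.tsv")) &&
      !overwrite) {
    abort_argument(sprintf("directory '%s' already holds a study; use overwrite = TRUE",
                           dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gene_model(study$gene_model, p(study_files["gene_model"]))
  write_matrix(study$expression, p(study_files["expression"]))
  write_design(study$design_expression, p(study_files["design_expression"]))
  write_seg(study$segments, p(study_files["segments"]))
  write_design(study$design_cnv, p(study_files["design_cnv"]))
  write_matrix(study$beta_a, p(study_files["beta_a"]))
  write_tsv_det(study$probe_map_a, p(study_files["probe_map_a"]))
  write_design(study$design_me_a, p(study_files["design_me_a"]))
  write_matrix(study$beta_b, p(study_files["beta_b"]))
  write_tsv_det(study$probe_map_b, p(study_files["probe_map_b"]))
  write_design(study$design_me_b, p(study_files["design_me_b"]))
  write_matrix(study$mirna, p(study_files["mirna"]))
  write_design(study$design_mirna, p(study_files["design_mirna"]))
  write_target_map(study$target_map, p(study_files["target_map"]))
  write_maf(study$maf, p(study_files["maf"]))
  write_tsv_det(tibble(sample_id = study$background_samples,
                       is_case = as.integer(study$background_samples %in%
                                              study$case_samples)),
                p(study_files["maf_cohort"]))
  write_tsv_det(study$truth$features, p("truth_features.tsv"))
  write_tsv_det(study$truth$genes, p("truth_genes.tsv"))
  manifest <- tibble(file = unname(study_files))
  manifest <- bind_rows(manifest,
                        tibble(file = c("truth_features.tsv", "truth_genes.tsv")))
  write_tsv_det(manifest, p("MANIFEST.tsv"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return A list shaped like the output of [generate_study()] (truth tables
#'   included when present).
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  missing <- study_files[!file.exists(p(study_files))]
  if (length(missing) > 0) {
    abort_argument(sprintf("missing study input file(s): %s",
                           paste(missing, collapse = ", ")))
  }
  cohort <- read_tsv_chr(p(study_files["maf_cohort"]))
  is_case <- to_num_strict(cohort$is_case, "is_case") > 0
  out <- list(
    gene_model = read_gene_model(p(study_files["gene_model"])),
    expression = read_matrix(p(study_files["expression"]), "expression"),
    design_expression = read_design(p(study_files["design_expression"])),
    segments = read_seg(p(study_files["segments"])),
    design_cnv = read_design(p(study_files["design_cnv"])),
    beta_a = read_matrix(p(study_files["beta_a"]), "beta"),
    probe_map_a = read_tsv_chr(p(study_files["probe_map_a"])),
    design_me_a = read_design(p(study_files["design_me_a"])),
    beta_b = read_matrix(p(study_files["beta_b"]), "beta"),
    probe_map_b = read_tsv_chr(p(study_files["probe_map_b"])),
    design_me_b = read_design(p(study_files["design_me_b"])),
    mirna = read_matrix(p(study_files["mirna"]), "mirna"),
    design_mirna = read_design(p(study_files["design_mirna"])),
    target_map = read_target_map(p(study_files["target_map"])),
    maf = read_maf(p(study_files["maf"])),
    case_samples = cohort$sample_id[is_case],
    background_samples = cohort$sample_id)
  if (file.exists(p("truth_genes.tsv"))) {
    tf <- read_tsv_chr(p("truth_features.tsv"))
    tg <- read_tsv_chr(p("truth_genes.tsv"))
    tf$effect <- to_num_strict(tf$effect, "effect")
    for (m in c("GE", "CN", "ME", "MR", "GM")) tg[[m]] <- tg[[m]] == "TRUE"
    tg$expected_level <- suppressWarnings(as.integer(tg$expected_level))
    out$truth <- list(features = tf, genes = tg)
  }
  structure(out, class = "synthetic_study")
}
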