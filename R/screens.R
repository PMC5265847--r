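#' Modality screens
#'
#' The five per-modality hyperactivation screens. Each returns a
#' `screen_result` tibble with one row per tested feature: `modality`,
#' `feature_id`, `effect` (fold change, beta difference, or odds ratio), `p`,
#' `q` (BH over tested features; absent for the mutation screen, which uses
#' raw p), `called`, `tested`, and the group sizes used. A feature is called
#' only when the effect-size and significance thresholds are both satisfied.
#'
#' @name modality-screens
NULL

new_screen_result <- function(df, modality, config) {
  structure(as_tibble(df), modality = modality, config = config,
            class = c("screen_result", class(as_tibble(df))))
}

#' Extract the called feature IDs of a screen result
#'
#' @param result A `screen_result`.
#' @return Character vector of called feature IDs.
#' @export
called_features <- function(result) {
  sort(result$feature_id[result$called])
}

# Shared paired tumor-vs-normal screen on a value matrix: fold of group means,
# signed-rank p on paired differences, BH q over tested features. Genes with
# fewer than `min_pairs` usable pairs, mean(normal) == 0, or all-zero
# differences are reported untested.
paired_screen <- function(mat, design, fold_min, fdr_max, modality, config,
                          min_pairs = 3L) {
  pairs <- design_pairs(design, colnames(mat))
  Tm <- mat[, pairs$sample_id_tumor, drop = FALSE]
  Nm <- mat[, pairs$sample_id_normal, drop = FALSE]
  n_genes <- nrow(mat)
  fold <- rep(NA_real_, n_genes)
  p <- rep(NA_real_, n_genes)
  n_used <- integer(n_genes)
  tested <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    tv <- Tm[g, ]; nv <- Nm[g, ]
    ok <- !is.na(tv) & !is.na(nv)
    n_used[g] <- sum(ok)
    if (n_used[g] < min_pairs) next
    mn <- mean(nv[ok])
    if (mn == 0) next
    fold[g] <- mean(tv[ok]) / mn
    d <- tv[ok] - nv[ok]
    if (all(d == 0)) next  # constant differences: untested
    res <- wsr_core(d)
    p[g] <- res$p_value
    tested[g] <- TRUE
  }
  q <- rep(NA_real_, n_genes)
  q[tested] <- bh_fdr(p[tested])
  called <- tested & !is.na(fold) & fold >= fold_min & q <= fdr_max
  new_screen_result(
    tibble(modality = modality, feature_id = rownames(mat),
           effect = fold, p = p, q = q,
           called = called, tested = tested,
           n_case = n_used, n_comparison = n_used),
    modality, config)
}

#' Screen for upregulated genes (GE)
#'
#' Paired tumor-vs-normal expression screen: per gene, the fold change is the
#' ratio of group means over pairs with both values present, the p-value is a
#' Wilcoxon signed-rank test on the paired differences, and q is BH over all
#' tested genes. A gene is called when `fold >= ge_fold` and `q <= ge_fdr`.
#' Genes with fewer than three usable pairs, zero mean normal expression, or
#' identical paired values are reported untested.
#'
#' @param expr Expression `omics_tbl` (genes x samples) or equivalent data
#'   frame with `feature_id` first.
#' @param design A [sample_design()] with tumor/normal pairing.
#' @param config A [threshold_config()].
#' @return A `screen_result` tibble, modality `"GE"`.
#' @export
screen_expression <- function(expr, design, config = threshold_config()) {
  config <- as_threshold_config(config)
  mat <- om_values(expr)
  paired_screen(mat, design, config$ge_fold, config$ge_fdr, "GE", config)
}

#' Screen for copy-number gain (CN)
#'
#' As [screen_expression()], on gene-level linear copy numbers (see
#' [map_segments_to_genes()]) with the copy-number fold threshold (default
#' 1.2). Genes imputed neutral in every sample have constant differences and
#' are reported untested.
#'
#' @param copies Gene-level copy-number `omics_tbl`.
#' @inheritParams screen_expression
#' @return A `screen_result` tibble, modality `"CN"`.
#' @export
screen_copy_number <- function(copies, design, config = threshold_config()) {
  config <- as_threshold_config(config)
  mat <- om_values(copies)
  paired_screen(mat, design, config$cn_fold, config$cn_fdr, "CN", config)
}

#' Collapse probe-level beta values to gene level
#'
#' Gene beta per sample is the unweighted mean of its mapped probes with
#' non-missing values; a gene whose probes are all missing in a sample stays
#' missing. Probes absent from the map are dropped with a message.
#'
#' @param beta Probe-level beta `omics_tbl`.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`.
#' @return A gene-level beta `omics_tbl`.
#' @export
collapse_probes_to_genes <- function(beta, probe_map) {
  mat <- om_values(beta)
  map <- as_tibble(probe_map)[, c("probe_id", "gene_id")]
  keep <- rownames(mat) %in% map$probe_id
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("dropping %d unmapped probes", n_drop))
  }
  mat <- mat[keep, , drop = FALSE]
  gene_of <- map$gene_id[match(rownames(mat), map$probe_id)]
  genes <- sort(unique(gene_of))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(mat),
                dimnames = list(genes, colnames(mat)))
  gidx <- match(gene_of, genes)
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    ok <- !is.na(v)
    if (!any(ok)) next
    sums <- rowsum(v[ok], gidx[ok])
    counts <- rowsum(rep(1, sum(ok)), gidx[ok])
    out[as.integer(rownames(sums)), j] <- sums[, 1] / counts[, 1]
  }
  omics_matrix(out, kind = "beta")
}

me_platform_stats <- function(mat, design) {
  grp <- design_groups(design, colnames(mat), min_n = 1L)
  Tm <- mat[, grp$tumor, drop = FALSE]
  Nm <- mat[, grp$normal, drop = FALSE]
  n <- nrow(mat)
  delta <- rep(NA_real_, n); p <- rep(NA_real_, n); tested <- logical(n)
  n_t <- integer(n); n_n <- integer(n)
  for (g in seq_len(n)) {
    tv <- Tm[g, ]; nv <- Nm[g, ]
    tv <- tv[!is.na(tv)]; nv <- nv[!is.na(nv)]
    n_t[g] <- length(tv); n_n[g] <- length(nv)
    if (length(tv) == 0L || length(nv) == 0L) next
    delta[g] <- mean(nv) - mean(tv)
    res <- wrs_core(tv, nv)
    p[g] <- res$p_value
    tested[g] <- TRUE
  }
  q <- rep(NA_real_, n)
  q[tested] <- bh_fdr(p[tested])
  tibble(feature_id = rownames(mat), delta = delta, p = p, q = q,
         tested = tested, n_tumor = n_t, n_normal = n_n)
}

#' Screen for hypomethylated genes on two platforms (ME)
#'
#' Per platform: the effect is the normal-minus-tumor mean beta difference,
#' the p-value a Wilcoxon rank-sum test between the (unpaired) tumor and
#' normal groups, and q is BH within the platform. A gene is called only when
#' on BOTH platforms the beta depression is at least `me_delta_beta` and
#' `q <= me_fdr` -- the intersection of the two per-platform analyses. The
#' result keeps the per-platform statistics (`_a`, `_b` suffixes); `effect` is
#' the smaller of the two beta differences (the binding constraint).
#'
#' @param beta_a,beta_b Gene-level beta `omics_tbl`s for the two platforms.
#' @param design_a,design_b Matching [sample_design()]s (unpaired groups).
#' @inheritParams screen_expression
#' @return A `screen_result` tibble, modality `"ME"`.
#' @export
screen_methylation <- function(beta_a, beta_b, design_a, design_b,
                               config = threshold_config()) {
  config <- as_threshold_config(config)
  a <- me_platform_stats(om_values(beta_a), design_a)
  b <- me_platform_stats(om_values(beta_b), design_b)
  all_genes <- sort(union(a$feature_id, b$feature_id))
  a <- a[match(all_genes, a$feature_id), ]
  b <- b[match(all_genes, b$feature_id), ]
  ok_a <- !is.na(a$tested) & a$tested
  ok_b <- !is.na(b$tested) & b$tested
  pass_a <- ok_a & !is.na(a$delta) & a$delta >= config$me_delta_beta &
    a$q <= config$me_fdr
  pass_b <- ok_b & !is.na(b$delta) & b$delta >= config$me_delta_beta &
    b$q <= config$me_fdr
  called <- pass_a & pass_b
  new_screen_result(
    tibble(modality = "ME", feature_id = all_genes,
           effect = pmin(a$delta, b$delta),
           p = pmax(a$p, b$p), q = pmax(a$q, b$q),
           delta_a = a$delta, p_a = a$p, q_a = a$q,
           delta_b = b$delta, p_b = b$p, q_b = b$q,
           called = called, tested = ok_a & ok_b,
           n_case = pmin(a$n_tumor, b$n_tumor),
           n_comparison = pmin(a$n_normal, b$n_normal)),
    "ME", config)
}

#' Screen for downregulated miRNAs (MR step 1)
#'
#' Unpaired tumor-vs-normal miRNA screen: the fold is the normal/tumor ratio
#' of raw group means; the p-value is a two-sample t test (Welch by default)
#' on log2(x + 1)-transformed values; q is BH over tested miRNAs. A miRNA is
#' called (downregulated in tumors) when `fold >= mr_fold` and `q <= mr_fdr`.
#' Constant miRNAs yield a degenerate p of 1 and are never called.
#'
#' @param mirna miRNA expression `omics_tbl`.
#' @param design A [sample_design()] (unpaired; pairing ignored).
#' @inheritParams screen_expression
#' @return A `screen_result` tibble, modality `"MR"` (features are miRNAs).
#' @export
screen_mirna <- function(mirna, design, config = threshold_config()) {
  config <- as_threshold_config(config)
  mat <- om_values(mirna)
  grp <- design_groups(design, colnames(mat), min_n = 2L)
  Tm <- mat[, grp$tumor, drop = FALSE]
  Nm <- mat[, grp$normal, drop = FALSE]
  n <- nrow(mat)
  fold <- rep(NA_real_, n); p <- rep(NA_real_, n); tested <- logical(n)
  n_t <- integer(n); n_n <- integer(n)
  var_equal <- config$t_variant == "student"
  for (g in seq_len(n)) {
    tv <- Tm[g, ]; nv <- Nm[g, ]
    tv <- tv[!is.na(tv)]; nv <- nv[!is.na(nv)]
    n_t[g] <- length(tv); n_n[g] <- length(nv)
    if (length(tv) < 2L || length(nv) < 2L) next
    mt <- mean(tv)
    fold[g] <- if (mt == 0) Inf else mean(nv) / mt
    res <- tt_core(log2(nv + 1), log2(tv + 1), var_equal = var_equal)
    p[g] <- res$p_value
    tested[g] <- TRUE
  }
  q <- rep(NA_real_, n)
  q[tested] <- bh_fdr(p[tested])
  called <- tested & !is.na(fold) & fold >= config$mr_fold & q <= config$mr_fdr
  new_screen_result(
    tibble(modality = "MR", feature_id = rownames(mat),
           effect = fold, p = p, q = q, called = called, tested = tested,
           n_case = n_t, n_comparison = n_n),
    "MR", config)
}

#' Map downregulated miRNAs to their target genes (MR step 2)
#'
#' The MR gene set is the union of the target sets of the called miRNAs.
#' Called miRNAs absent from the target map contribute nothing and trigger a
#' warning.
#'
#' @param down_mirnas Character vector of called miRNA IDs, or a `screen_result`
#'   from [screen_mirna()] (its called features are used).
#' @param targets Target map tibble (`mirna_id`, `gene_id`) as from
#'   [read_target_map()].
#' @return Sorted character vector of target gene IDs.
#' @export
map_mirna_targets <- function(down_mirnas, targets) {
  if (inherits(down_mirnas, "screen_result")) {
    down_mirnas <- called_features(down_mirnas)
  }
  if (length(down_mirnas) == 0L) return(character(0))
  tl <- target_list(targets)
  missing <- setdiff(down_mirnas, names(tl))
  if (length(missing) > 0) {
    warn(sprintf("%d called miRNA(s) absent from the target map: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  sort(unique(unlist(tl[intersect(down_mirnas, names(tl))], use.names = FALSE)))
}
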