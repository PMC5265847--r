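#' Build a binary gene-by-sample mutation matrix
#'
#' Entry (i, j) is 1 if at least one qualifying mutation call for gene i was
#' observed in sample j, otherwise 0. Duplicate calls collapse to 1. Calls for
#' samples outside the supplied sample list are dropped with a message. Rows
#' are restricted to genes with at least one retained call; the full sample
#' list is kept as columns (so mutation rates are over the whole cohort).
#'
#' @param calls Mutation-call tibble as from [read_maf()].
#' @param samples Ordered character vector of cohort sample IDs.
#' @param classification_filter Which Variant_Classification values qualify:
#'   `"non_silent"` (default; everything except `"Silent"`), `"all"`, or a
#'   character vector of classifications to retain.
#' @return A binary integer matrix of class `mutation_matrix`.
#' @export
build_mutation_matrix <- function(calls, samples,
                                  classification_filter = "non_silent") {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort_argument("cohort sample IDs must be unique")
  calls <- as_tibble(calls)
  if (length(classification_filter) == 1L && classification_filter == "all") {
    keep_class <- rep(TRUE, nrow(calls))
  } else if (length(classification_filter) == 1L &&
             classification_filter == "non_silent") {
    keep_class <- is.na(calls$variant_classification) |
      calls$variant_classification != "Silent"
  } else {
    keep_class <- calls$variant_classification %in% classification_filter
  }
  calls <- calls[keep_class, ]
  in_cohort <- calls$sample_id %in% samples
  if (any(!in_cohort)) {
    inform(sprintf("dropping %d call(s) for samples outside the cohort",
                   sum(!in_cohort)))
  }
  calls <- calls[in_cohort, ]
  genes <- sort(unique(calls$gene_id))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(calls) > 0) {
    mat[cbind(match(calls$gene_id, genes), match(calls$sample_id, samples))] <- 1L
  }
  structure(mat, class = c("mutation_matrix", class(mat)))
}

#' Screen for mutation-enriched genes (GM)
#'
#' Per gene, a 2x2 table (case mutated, case wild-type; background mutated,
#' background wild-type) is tested with Fisher's exact test; the effect is the
#' sample odds ratio. By default the background is the full cohort including
#' the case samples (the convention under which a 78%-of-54 vs 31%-of-992
#' TP53-style comparison is arithmetically consistent). A gene is called when
#' `p < gm_p` and the odds ratio exceeds 1. No FDR is applied (raw p, as is
#' conventional for this screen); set `gm_use_fdr = TRUE` in the config to
#' also report BH q (the call still uses raw p).
#'
#' @param case_matrix `mutation_matrix` over the case (e.g. TNBC) samples.
#' @param background_matrix `mutation_matrix` over the background cohort.
#' @inheritParams screen_expression
#' @return A `screen_result` tibble, modality `"GM"`, with columns
#'   `n_mut_case` and `n_mut_background` in addition to the shared schema.
#' @export
screen_mutations <- function(case_matrix, background_matrix,
                             config = threshold_config()) {
  config <- as_threshold_config(config)
  n_case <- ncol(case_matrix)
  n_bg <- ncol(background_matrix)
  if (n_case == 0L) abort_argument("case cohort has zero samples")
  if (n_bg == 0L) abort_argument("background cohort has zero samples")
  genes <- sort(union(rownames(case_matrix), rownames(background_matrix)))
  a <- integer(length(genes))
  cc <- integer(length(genes))
  hit <- match(genes, rownames(case_matrix))
  a[!is.na(hit)] <- rowSums(case_matrix)[hit[!is.na(hit)]]
  hit <- match(genes, rownames(background_matrix))
  cc[!is.na(hit)] <- rowSums(background_matrix)[hit[!is.na(hit)]]
  or <- rep(NA_real_, length(genes))
  p <- rep(NA_real_, length(genes))
  for (g in seq_along(genes)) {
    res <- fisher_core(a[g], n_case - a[g], cc[g], n_bg - cc[g])
    or[g] <- res$odds_ratio
    p[g] <- res$p_value
  }
  called <- !is.na(or) & or > 1 & p < config$gm_p
  df <- tibble(modality = "GM", feature_id = genes, effect = or, p = p,
               called = called, tested = TRUE,
               n_case = n_case, n_comparison = n_bg,
               n_mut_case = a, n_mut_background = cc)
  if (config$gm_use_fdr) df$q <- bh_fdr(p)
  new_screen_result(df, "GM", config)
}
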