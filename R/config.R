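#' Screen thresholds
#'
#' Effect-size and significance thresholds for the five modality screens.
#' Defaults are the canonical screen settings: two-fold expression elevation at
#' FDR <= 0.05 (paired signed-rank), 1.2-fold copy-number gain at FDR <= 0.05
#' (paired signed-rank; copy-number folds are small, rarely above 1.5), a
#' beta-value depression of at least 5% at FDR <= 0.05 on both methylation
#' platforms (rank-sum), two-fold miRNA downregulation at FDR <= 0.05 (t test
#' on log2(x+1) values), and raw Fisher p < 0.05 with odds ratio > 1 for
#' mutation enrichment.
#'
#' @param ge_fold,ge_fdr Expression fold (tumor/normal mean ratio) and FDR cut.
#' @param cn_fold,cn_fdr Linear copy-number fold and FDR cut.
#' @param me_delta_beta,me_fdr Minimum normal-minus-tumor mean beta difference
#'   and per-platform FDR cut.
#' @param mr_fold,mr_fdr miRNA fold (normal/tumor mean ratio) and FDR cut.
#' @param gm_p Raw Fisher p cutoff for the mutation screen (no FDR).
#' @param t_variant `"welch"` (default) or `"student"` for the miRNA t test.
#' @param cn_weighted Length-weight the segment average when mapping segments
#'   to genes (`TRUE`) or use the unweighted mean (`FALSE`).
#' @param gm_use_fdr Additionally compute BH q for the mutation screen (the
#'   call still uses the raw p).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(ge_fold = 2.0, ge_fdr = 0.05,
                             cn_fold = 1.2, cn_fdr = 0.05,
                             me_delta_beta = 0.05, me_fdr = 0.05,
                             mr_fold = 2.0, mr_fdr = 0.05,
                             gm_p = 0.05,
                             t_variant = c("welch", "student"),
                             cn_weighted = TRUE,
                             gm_use_fdr = FALSE) {
  t_variant <- match.arg(t_variant)
  cfg <- list(ge_fold = ge_fold, ge_fdr = ge_fdr,
              cn_fold = cn_fold, cn_fdr = cn_fdr,
              me_delta_beta = me_delta_beta, me_fdr = me_fdr,
              mr_fold = mr_fold, mr_fdr = mr_fdr,
              gm_p = gm_p, t_variant = t_variant,
              cn_weighted = isTRUE(cn_weighted),
              gm_use_fdr = isTRUE(gm_use_fdr))
  for (f in c("ge_fold", "cn_fold", "mr_fold")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 1) {
      abort_validation(sprintf("`%s` must be greater than 1", f))
    }
  }
  for (f in c("ge_fdr", "cn_fdr", "me_fdr", "mr_fdr", "gm_p")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      abort_validation(sprintf("`%s` must lie in (0, 1)", f))
    }
  }
  if (!is.numeric(cfg$me_delta_beta) || cfg$me_delta_beta <= 0 || cfg$me_delta_beta >= 1) {
    abort_validation("`me_delta_beta` must lie in (0, 1)")
  }
  structure(cfg, class = "threshold_config")
}

as_threshold_config <- function(x) {
  if (inherits(x, "threshold_config")) return(x)
  if (is.list(x)) return(do.call(threshold_config, x))
  abort_argument("cannot interpret `config` as screen thresholds")
}
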