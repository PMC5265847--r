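#' Annotate genes with copy number from segmented data
#'
#' Converts each segment mean from the log2(copy/2) scale to a linear copy
#' number `2 * 2^seg_value`, intersects segments with the gene model, and
#' averages the linear copies of the segments overlapping each gene --
#' length-weighted by the number of overlapping bases (1-based inclusive
#' widths) by default, or unweighted. Genes with no covering segment in a
#' sample are imputed at the neutral diploid value 2 and flagged, because
#' "nocnv"-style files omit copy-neutral regions.
#'
#' Chromosome names are matched verbatim; if the segments and the gene model
#' share no chromosome at all, every value is imputed and a warning is raised.
#'
#' @param segments Segment tibble as from [read_seg()]: `sample_id`, `chrom`,
#'   `start`, `end`, `seg_value`.
#' @param genes Gene-model tibble as from [read_gene_model()].
#' @param weighted Length-weight the average (default) or not.
#' @param neutral_copy Linear copy imputed where a gene has no overlap.
#' @return An `omics_tbl` of kind `"copy_number"` (genes x samples) with a
#'   logical attribute `imputed` of the same shape marking imputed cells.
#' @export
map_segments_to_genes <- function(segments, genes, weighted = TRUE,
                                  neutral_copy = 2) {
  validate_gene_model(genes)
  samples <- unique(segments$sample_id)
  mat <- matrix(neutral_copy, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
  imputed <- matrix(TRUE, nrow = nrow(genes), ncol = length(samples),
                    dimnames = list(genes$gene_id, samples))
  if (nrow(segments) > 0) {
    if (!any(segments$chrom %in% genes$chrom)) {
      warn(paste("segments and gene model share no chromosome;",
                 "all copy numbers imputed neutral"))
    }
    seg_gr <- GenomicRanges::GRanges(
      seqnames = segments$chrom,
      ranges = IRanges::IRanges(start = segments$start, end = segments$end))
    gene_gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr))
    if (length(hits) > 0) {
      gi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov_width <- pmin(genes$end[gi], segments$end[si]) -
        pmax(genes$start[gi], segments$start[si]) + 1L
      df <- tibble(gene = gi, sample = match(segments$sample_id[si], samples),
                   copy = 2 * 2^segments$seg_value[si],
                   w = if (weighted) as.numeric(ov_width) else 1)
      agg <- df %>%
        group_by(.data$gene, .data$sample) %>%
        summarise(copy = sum(.data$copy * .data$w) / sum(.data$w),
                  .groups = "drop")
      idx <- cbind(agg$gene, agg$sample)
      mat[idx] <- agg$copy
      imputed[idx] <- FALSE
    }
  }
  out <- omics_matrix(mat, kind = "copy_number")
  attr(out, "imputed") <- imputed
  out
}

#' Fraction of imputed (no-overlap) cells per gene
#'
#' @param copies Result of [map_segments_to_genes()].
#' @return A tibble: `feature_id`, `imputed_fraction`.
#' @export
imputed_fraction <- function(copies) {
  imp <- attr(copies, "imputed", exact = TRUE)
  if (is.null(imp)) abort_argument("`copies` carries no imputation flags")
  tibble(feature_id = rownames(imp), imputed_fraction = unname(rowMeans(imp)))
}
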