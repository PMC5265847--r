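#' Evidence integration
#'
#' Fuses the five called gene sets (GE, CN, ME, MR, GM) into a gene-by-modality
#' evidence table and assigns each highly-expressed gene a nested evidence
#' level: Level 1 = called in GE; Level k (k = 2..5) = Level 1 plus
#' hyperactivation evidence from at least k - 1 of the other four modalities.
#' Level sets are nested: a Level-3 gene is also a member of Levels 1 and 2.
#'
#' @name evidence-integration
NULL

#' Build the gene-by-modality evidence table
#'
#' @param ge,cn,me,mr,gm Character vectors of called gene IDs per modality
#'   (or `screen_result`s, whose called features are taken; `mr` as a
#'   character vector should be the mapped target-gene set).
#' @return A tibble of class `evidence_table`: `gene_id` plus logical columns
#'   `GE`, `CN`, `ME`, `MR`, `GM`, one row per gene in the union, sorted by
#'   gene ID.
#' @export
build_evidence_table <- function(ge, cn, me, mr, gm) {
  as_set <- function(x) {
    if (inherits(x, "screen_result")) x <- called_features(x)
    unique(as.character(x))
  }
  sets <- list(GE = as_set(ge), CN = as_set(cn), ME = as_set(me),
               MR = as_set(mr), GM = as_set(gm))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  out <- tibble(gene_id = genes)
  for (m in names(sets)) out[[m]] <- genes %in% sets[[m]]
  structure(out, class = c("evidence_table", class(out)))
}

#' Assign nested evidence levels
#'
#' Genes called in GE receive level `1 + k` where `k` is the number of other
#' modalities (CN, ME, MR, GM) with evidence; genes not in GE receive no
#' level. The returned tibble reports each gene's highest ("exact") level;
#' nested membership counts are available via [level_counts()] and per-level
#' member lists via [level_members()].
#'
#' @param table An `evidence_table`.
#' @return A tibble of class `level_assignment`: `gene_id`, `level`.
#' @export
assign_levels <- function(table) {
  stopifnot(inherits(table, "evidence_table") ||
              all(c("gene_id", "GE", "CN", "ME", "MR", "GM") %in% names(table)))
  ge <- table$GE
  others <- as.matrix(table[, c("CN", "ME", "MR", "GM")])
  out <- tibble(gene_id = table$gene_id[ge],
                level = 1L + as.integer(rowSums(others[ge, , drop = FALSE])))
  out <- arrange(out, dplyr::desc(.data$level), .data$gene_id)
  structure(out, class = c("level_assignment", class(out)))
}

#' Per-level gene counts
#'
#' With `nested = TRUE` (the canonical output) the count at level k is the
#' number of GE genes with other-modality evidence from at least k - 1
#' modalities, so counts are monotone non-increasing in k. With
#' `nested = FALSE` each gene is counted only at its highest level.
#'
#' @param levels A `level_assignment`.
#' @param nested Nested membership counts (default) or exact-level counts.
#' @return A tibble: `level` (1..5), `n`.
#' @export
level_counts <- function(levels, nested = TRUE) {
  k <- 1:5
  n <- if (nested) {
    vapply(k, function(l) sum(levels$level >= l), integer(1))
  } else {
    vapply(k, function(l) sum(levels$level == l), integer(1))
  }
  tibble(level = k, n = n)
}

#' @rdname level_counts
#' @param k Level of interest.
#' @return For `level_members()`: sorted gene IDs with level at least `k`
#'   (nested membership).
#' @export
level_members <- function(levels, k, nested = TRUE) {
  if (nested) sort(levels$gene_id[levels$level >= k])
  else sort(levels$gene_id[levels$level == k])
}

#' Count genes shared by modality combinations
#'
#' For each requested subset of modalities, the number of genes with evidence
#' in ALL of them (inclusive intersections, not exclusive Venn regions). The
#' default combinations are all pairs containing GE and all triples
#' containing GE.
#'
#' @param table An `evidence_table`.
#' @param combos List of character vectors of modality names, or `NULL` for
#'   the default.
#' @return A tibble: `combo` (e.g. `"GE+CN"`), `n`.
#' @export
overlap_counts <- function(table, combos = NULL) {
  mods <- c("GE", "CN", "ME", "MR", "GM")
  if (is.null(combos)) {
    others <- setdiff(mods, "GE")
    combos <- c(lapply(others, function(m) c("GE", m)),
                utils::combn(others, 2, function(p) c("GE", p), simplify = FALSE))
  }
  bad <- vapply(combos, function(cm) !all(cm %in% mods), logical(1))
  if (any(bad)) abort_argument("unknown modality in `combos`")
  n <- vapply(combos, function(cm) {
    sum(Reduce(`&`, lapply(cm, function(m) table[[m]])))
  }, numeric(1))
  tibble(combo = vapply(combos, paste, character(1), collapse = "+"),
         n = as.integer(n))
}

#' Export the Level >= 3 evidence heatmap table
#'
#' Rows are genes at nested Level 3 or higher, sorted by level (descending)
#' then gene ID; cells are 0/1 hyperactivation flags per modality. Returns
#' the table invisibly; writes a TSV when `path` is given. Plot rendering is
#' available separately via [autoplot.evidence_table()].
#'
#' @param table An `evidence_table`.
#' @param path Optional output TSV path.
#' @param min_level Minimum nested level to include.
#' @return A tibble: `gene_id`, `level`, `GE`, `CN`, `ME`, `MR`, `GM` (0/1).
#' @export
export_evidence_heatmap <- function(table, path = NULL, min_level = 3L) {
  lv <- assign_levels(table)
  keep <- level_members(lv, min_level)
  df <- as_tibble(table)[match(keep, table$gene_id), , drop = FALSE]
  df <- dplyr::bind_cols(
    tibble(gene_id = df$gene_id,
           level = lv$level[match(df$gene_id, lv$gene_id)]),
    df[, c("GE", "CN", "ME", "MR", "GM")])
  for (m in c("GE", "CN", "ME", "MR", "GM")) df[[m]] <- as.integer(df[[m]])
  df <- arrange(df, dplyr::desc(.data$level), .data$gene_id)
  if (!is.null(path)) write_tsv_det(df, path)
  invisible(df)
}
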