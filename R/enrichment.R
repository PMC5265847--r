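#' Gene-set overlap enrichment
#'
#' Hypergeometric "compute overlaps" enrichment of a query gene list against a
#' gene-set collection: each set is intersected with the universe, the overlap
#' with the query is scored by the hypergeometric upper tail, and BH q-values
#' are computed across all sets. The default reporting filter is a very
#' stringent FDR < 1e-10, appropriate for large curated collections; the
#' universe should normally be the set of genes actually tested in the
#' expression screen.
#'
#' @param query Character vector of query gene IDs.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of background gene IDs. Query genes
#'   outside the universe are dropped with a warning.
#' @param fdr_cutoff Significance filter marking reported sets.
#' @return A tibble sorted by q then set name: `set_name`, `set_size`
#'   (within the universe), `query_size`, `overlap`, `p`, `q`, `significant`.
#' @export
enrich_overlap <- function(query, collection, universe, fdr_cutoff = 1e-10) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort_argument("`universe` is empty")
  if (length(query) == 0L) abort_argument("`query` is empty")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("dropping %d query gene(s) outside the universe", length(outside)))
    query <- intersect(query, universe)
    if (length(query) == 0L) abort_argument("no query genes inside the universe")
  }
  if (length(collection) == 0L) abort_argument("`collection` is empty")
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    abort_argument("`collection` must be a uniquely named list of gene sets")
  }
  rows <- purrr::map(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    ov <- length(intersect(s, query))
    tibble(set_name = nm, set_size = length(s), query_size = length(query),
           overlap = ov,
           p = hypergeom_overlap_p(length(universe), length(s),
                                   length(query), ov))
  })
  out <- bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_cutoff
  arrange(out, .data$q, .data$set_name)
}
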