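#' Omics matrix tibbles
#'
#' The pipeline carries feature-by-sample matrices as tibbles whose first
#' column is `feature_id` and whose remaining columns are samples, with a
#' `kind` attribute in `c("expression", "copy_number", "beta", "mirna")`.
#' Construction validates the kind's value range: beta values must lie in
#' \[0, 1\], expression/miRNA values must be non-negative, copy numbers must be
#' positive; missing values are allowed everywhere and excluded pairwise from
#' downstream group statistics.
#'
#' @param x A data frame with a `feature_id` first column and numeric sample
#'   columns, or a numeric matrix with feature rownames and sample colnames.
#' @param kind One of `"expression"`, `"copy_number"`, `"beta"`, `"mirna"`.
#' @return A tibble of class `omics_tbl` with attribute `kind`.
#' @export
omics_matrix <- function(x, kind) {
  kind <- match.arg(kind, c("expression", "copy_number", "beta", "mirna"))
  if (is.matrix(x)) {
    if ((is.null(rownames(x)) && nrow(x) > 0) || is.null(colnames(x))) {
      abort_argument("matrix input needs feature rownames and sample colnames")
    }
    x <- dplyr::bind_cols(tibble(feature_id = rownames(x) %||% character(0)),
                          as_tibble(x, .name_repair = "minimal"))
  }
  if (!is.data.frame(x)) abort_argument("`x` must be a data frame or matrix")
  x <- as_tibble(x)
  if (names(x)[1] != "feature_id") names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  if (anyDuplicated(x$feature_id)) {
    dup <- x$feature_id[duplicated(x$feature_id)][1]
    abort_format(sprintf("duplicate feature ID '%s'", dup))
  }
  if (ncol(x) < 2L) abort_argument("omics matrix needs at least one sample column")
  if (anyDuplicated(names(x)[-1])) abort_format("duplicate sample IDs")
  for (j in seq(2L, ncol(x))) {
    if (!is.numeric(x[[j]])) {
      abort_format(sprintf("sample column '%s' is not numeric", names(x)[j]))
    }
  }
  vals <- om_values(x)
  check_kind_values(vals, kind)
  structure(x, kind = kind, class = c("omics_tbl", class(x)))
}

check_kind_values <- function(vals, kind) {
  v <- vals[!is.na(vals)]
  if (kind == "beta" && any(v < 0 | v > 1)) {
    abort_validation(sprintf("beta value %g outside [0, 1]", v[v < 0 | v > 1][1]))
  }
  if (kind %in% c("expression", "mirna") && any(v < 0)) {
    abort_validation(sprintf("%s value %g is negative", kind, v[v < 0][1]))
  }
  if (kind == "copy_number" && any(v <= 0)) {
    abort_validation(sprintf("copy number value %g is not positive", v[v <= 0][1]))
  }
  invisible(TRUE)
}

#' Extract the numeric value matrix of an omics tibble
#'
#' @param x An `omics_tbl` (or any feature_id-first data frame).
#' @return A numeric matrix, features x samples, with dimnames.
#' @export
om_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

#' @export
#' @rdname om_values
om_kind <- function(x) attr(x, "kind", exact = TRUE)

#' @export
#' @rdname om_values
om_samples <- function(x) names(x)[-1]

#' Sample design for a tumor/normal cohort
#'
#' @param sample_id Character vector of sample IDs (unique).
#' @param group `"tumor"` or `"normal"` per sample.
#' @param pair_id Optional pairing key linking each tumor to its matched
#'   normal; required by the paired screens.
#' @return A tibble of class `sample_design`.
#' @export
sample_design <- function(sample_id, group, pair_id = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) abort_argument("sample IDs must be unique")
  if (!all(group %in% c("tumor", "normal"))) {
    abort_argument("`group` values must be 'tumor' or 'normal'")
  }
  d <- tibble(sample_id = sample_id, group = as.character(group))
  if (!is.null(pair_id)) d$pair_id <- as.character(pair_id)
  structure(d, class = c("sample_design", class(d)))
}

# Aligned (tumor, normal) sample-ID vectors for the samples present in the
# matrix; errors when no complete pair survives.
design_pairs <- function(design, samples) {
  if (!"pair_id" %in% names(design)) {
    abort_argument("paired screens need a `pair_id` column in the design")
  }
  d <- design[design$sample_id %in% samples & !is.na(design$pair_id), ]
  tum <- d[d$group == "tumor", c("pair_id", "sample_id")]
  nor <- d[d$group == "normal", c("pair_id", "sample_id")]
  pairs <- dplyr::inner_join(tum, nor, by = "pair_id",
                             suffix = c("_tumor", "_normal"))
  if (nrow(pairs) == 0L) abort_argument("no complete tumor/normal pairs in the design")
  pairs
}

design_groups <- function(design, samples, min_n = 1L) {
  d <- design[design$sample_id %in% samples, ]
  tum <- d$sample_id[d$group == "tumor"]
  nor <- d$sample_id[d$group == "normal"]
  if (length(tum) < min_n || length(nor) < min_n) {
    abort_argument(sprintf("need at least %d tumor and %d normal samples", min_n, min_n))
  }
  list(tumor = tum, normal = nor)
}
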