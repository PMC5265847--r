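#' File formats
#'
#' Readers and writers for every external format the pipeline touches: SEG
#' (segmented copy number), MAF (somatic mutation calls), BED-like gene
#' models, GMT gene-set collections, two-column miRNA target maps, and plain
#' TSV feature-by-sample matrices and result tables.
#'
#' Internal genomic coordinates are 1-based inclusive (SEG-native); BED input
#' is converted at the boundary (`start + 1`, `end`). Chromosome names are
#' taken verbatim, with no "chr" normalization. All writers are
#' byte-deterministic (fixed column order, fixed numeric formatting, sorted
#' rows where a sort is defined) so outputs diff cleanly.
#'
#' @name io-formats
NULL

match_col <- function(df, name, path, required = TRUE) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (length(hit) == 0L) {
    if (required) {
      abort_format(sprintf("missing required column '%s' in %s", name, path))
    }
    return(NA_integer_)
  }
  hit[1]
}

#' Read a SEG file of copy-number segments
#'
#' Tab-delimited with header columns Sample, Chromosome, Start, End,
#' optionally Num_Probes, and Segment_Mean (case-insensitive). Coordinates are
#' 1-based inclusive; the segment mean is a log2(copy/2) ratio. Segments
#' belonging to one sample must not overlap on the same chromosome.
#'
#' @param path Path to the SEG file.
#' @return A tibble: `sample_id`, `chrom`, `start`, `end`, `seg_value`
#'   (and `num_probes` when present).
#' @export
read_seg <- function(path) {
  raw <- read_tsv_chr(path)
  i_sample <- match_col(raw, "Sample", path)
  i_chrom <- match_col(raw, "Chromosome", path)
  i_start <- match_col(raw, "Start", path)
  i_end <- match_col(raw, "End", path)
  i_val <- match_col(raw, "Segment_Mean", path)
  i_np <- match_col(raw, "Num_Probes", path, required = FALSE)
  out <- tibble(
    sample_id = raw[[i_sample]],
    chrom = raw[[i_chrom]],
    start = to_num_strict(raw[[i_start]], "Start", "coordinate"),
    end = to_num_strict(raw[[i_end]], "End", "coordinate"),
    seg_value = to_num_strict(raw[[i_val]], "Segment_Mean")
  )
  if (!is.na(i_np)) out$num_probes <- to_num_strict(raw[[i_np]], "Num_Probes")
  if (any(out$start != round(out$start) | out$end != round(out$end))) {
    bad <- which(out$start != round(out$start) | out$end != round(out$end))[1]
    abort_format(sprintf("non-integer coordinate at line %d", bad + 1L))
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  validate_segments(out)
  out
}

validate_segments <- function(segs) {
  bad <- which(segs$end < segs$start)
  if (length(bad) > 0) {
    abort_format(sprintf("segment end < start at line %d", bad[1] + 1L))
  }
  if (any(!is.finite(segs$seg_value))) {
    abort_format("non-finite segment value")
  }
  if (any(is.na(segs$sample_id) | segs$sample_id == "")) {
    abort_format("empty sample ID in segment records")
  }
  if (any(is.na(segs$chrom) | segs$chrom == "")) {
    abort_format("empty chromosome in segment records")
  }
  by_sc <- split(segs, paste(segs$sample_id, segs$chrom, sep = "\r"))
  for (g in by_sc) {
    if (nrow(g) < 2L) next
    o <- order(g$start)
    if (any(g$start[o][-1] <= g$end[o][-nrow(g)])) {
      abort_format(sprintf(
        "overlapping segments for sample '%s' on chromosome '%s'",
        g$sample_id[1], g$chrom[1]))
    }
  }
  invisible(segs)
}

#' Write segments as a SEG file
#'
#' @param segments Tibble as returned by [read_seg()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  out <- tibble(Sample = segments$sample_id, Chromosome = segments$chrom,
                Start = as.integer(segments$start), End = as.integer(segments$end))
  if ("num_probes" %in% names(segments)) out$Num_Probes <- segments$num_probes
  out$Segment_Mean <- segments$seg_value
  write_tsv_det(out, path)
}

#' Read a MAF file of somatic mutation calls
#'
#' Requires the Hugo_Symbol, Tumor_Sample_Barcode and Variant_Classification
#' columns. Duplicate (gene, sample) rows are preserved; deduplication happens
#' when the mutation matrix is built. A header-only file yields an empty
#' tibble.
#'
#' @param path Path to the MAF file.
#' @return A tibble: `gene_id`, `sample_id`, `variant_classification`.
#' @export
read_maf <- function(path) {
  raw <- read_tsv_chr(path)
  i_gene <- match_col(raw, "Hugo_Symbol", path)
  i_sample <- match_col(raw, "Tumor_Sample_Barcode", path)
  i_class <- match_col(raw, "Variant_Classification", path)
  gene <- raw[[i_gene]]
  samp <- raw[[i_sample]]
  bad <- which(is.na(gene) | gene == "" | is.na(samp) | samp == "")
  if (length(bad) > 0) {
    abort_format(sprintf("empty Hugo_Symbol or Tumor_Sample_Barcode at row %d", bad[1]))
  }
  tibble(gene_id = gene, sample_id = samp,
         variant_classification = raw[[i_class]])
}

#' @rdname read_maf
#' @param calls Tibble of mutation calls.
#' @export
write_maf <- function(calls, path) {
  out <- tibble(Hugo_Symbol = calls$gene_id,
                Variant_Classification = calls$variant_classification,
                Tumor_Sample_Barcode = calls$sample_id)
  write_tsv_det(out, path)
}

#' Read a feature-by-sample TSV matrix
#'
#' First column is the feature ID, remaining columns are samples; `NA` cells
#' mark missing values, which stay missing and are excluded from downstream
#' group statistics. Values are validated against the declared kind (see
#' [omics_matrix()]).
#'
#' @param path Path to the TSV.
#' @param kind Matrix kind: `"expression"`, `"copy_number"`, `"beta"`, `"mirna"`.
#' @return An `omics_tbl`.
#' @export
read_matrix <- function(path, kind) {
  raw <- read_tsv_chr(path)
  if (ncol(raw) < 2L) abort_format(sprintf("matrix %s has no sample columns", path))
  out <- raw[, 1, drop = FALSE]
  names(out)[1] <- "feature_id"
  for (j in seq(2L, ncol(raw))) {
    col <- raw[[j]]
    col[col == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0) {
      abort_format(sprintf("non-numeric value '%s' in column '%s' at line %d",
                           col[bad[1]], names(raw)[j], bad[1] + 1L))
    }
    out[[names(raw)[j]]] <- num
  }
  omics_matrix(out, kind = kind)
}

#' @rdname read_matrix
#' @param x An `omics_tbl` (or feature_id-first data frame).
#' @export
write_matrix <- function(x, path) {
  write_tsv_det(as_tibble(x), path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member genes (at
#' least one member). Set names must be unique.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file does not exist: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0) {
    abort_format(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    abort_format(sprintf("duplicate gene-set name '%s'", nms[duplicated(nms)][1]))
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection",
            descriptions = vapply(parts, `[[`, character(1), 2L))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column miRNA target map
#'
#' Tab-delimited with header `mirna_id`, `gene_id` (TargetScan-style,
#' flattened to pairs). Target sets may be empty for miRNAs absent from the
#' file; empty miRNA IDs are rejected.
#'
#' @param path Path to the TSV.
#' @return A tibble: `mirna_id`, `gene_id`.
#' @export
read_target_map <- function(path) {
  raw <- read_tsv_chr(path)
  i_m <- match_col(raw, "mirna_id", path)
  i_g <- match_col(raw, "gene_id", path)
  out <- tibble(mirna_id = raw[[i_m]], gene_id = raw[[i_g]])
  if (any(is.na(out$mirna_id) | out$mirna_id == "")) {
    abort_format("empty miRNA ID in target map")
  }
  distinct(out)
}

#' @rdname read_target_map
#' @param map Tibble with `mirna_id`, `gene_id`.
#' @export
write_target_map <- function(map, path) {
  write_tsv_det(arrange(as_tibble(map[, c("mirna_id", "gene_id")]),
                        .data$mirna_id, .data$gene_id), path)
}

# Target map tibble -> named list mirna_id -> character vector of targets
target_list <- function(map) {
  split(map$gene_id, map$mirna_id)
}

#' Read a BED-like gene model
#'
#' Headerless, tab-delimited: chrom, start (0-based), end (exclusive),
#' gene_id, optionally score and strand. Coordinates are converted to the
#' internal 1-based inclusive convention (`start + 1`, `end`).
#'
#' @param path Path to the BED file.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end` (and `strand` when
#'   present).
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file does not exist: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort_format("empty gene model")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 4L)
  if (length(short) > 0) {
    abort_format(sprintf("BED line %d has fewer than 4 fields", short[1]))
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- to_num_strict(vapply(parts, `[[`, character(1), 2L), "start", "coordinate")
  end0 <- to_num_strict(vapply(parts, `[[`, character(1), 3L), "end", "coordinate")
  gene <- vapply(parts, `[[`, character(1), 4L)
  bad <- which(start0 >= end0)
  if (length(bad) > 0) {
    abort_format(sprintf("BED start >= end at line %d", bad[1]))
  }
  out <- tibble(gene_id = gene, chrom = chrom,
                start = as.integer(start0 + 1L), end = as.integer(end0))
  if (any(lengths(parts) >= 6L)) {
    out$strand <- vapply(parts, function(p) if (length(p) >= 6L) p[[6L]] else ".",
                         character(1))
  }
  validate_gene_model(out)
  out
}

validate_gene_model <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    abort_format(sprintf("duplicate gene ID '%s' in gene model",
                         genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  if (any(genes$start > genes$end)) abort_format("gene start > end")
  if (any(is.na(genes$chrom) | genes$chrom == "")) abort_format("empty chromosome")
  invisible(genes)
}

#' @rdname read_gene_model
#' @param genes Gene-model tibble (internal 1-based inclusive coordinates).
#' @export
write_gene_model <- function(genes, path) {
  validate_gene_model(genes)
  strand <- if ("strand" %in% names(genes)) genes$strand else rep(".", nrow(genes))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                   as.integer(genes$start - 1L), as.integer(genes$end),
                   genes$gene_id, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-modality screen result table
#'
#' Deterministic TSV: fixed column order, 6-significant-digit floats, rows
#' sorted by q (then p, then feature ID).
#'
#' @param result A `screen_result` tibble.
#' @param path Output path.
#' @export
write_screen_result <- function(result, path) {
  df <- as_tibble(result)
  sort_key <- if ("q" %in% names(df)) df$q else df$p
  ord <- order(!df$tested, sort_key, df$p, df$feature_id, na.last = TRUE)
  write_tsv_det(df[ord, ], path, digits = 6L)
}

#' Write / read a gene-by-modality evidence table
#'
#' Cells are 0/1; rows sorted by gene ID. Reading back reproduces the
#' booleans exactly.
#'
#' @param table An `evidence_table` tibble.
#' @param path Path.
#' @export
write_evidence_table <- function(table, path) {
  df <- as_tibble(table)[, c("gene_id", "GE", "CN", "ME", "MR", "GM")]
  df <- arrange(df, .data$gene_id)
  for (m in c("GE", "CN", "ME", "MR", "GM")) df[[m]] <- as.integer(df[[m]])
  write_tsv_det(df, path)
}

#' @rdname write_evidence_table
#' @export
read_evidence_table <- function(path) {
  raw <- read_tsv_chr(path)
  for (m in c("gene_id", "GE", "CN", "ME", "MR", "GM")) {
    if (!m %in% names(raw)) abort_format(sprintf("missing column '%s'", m))
  }
  out <- tibble(gene_id = raw$gene_id)
  for (m in c("GE", "CN", "ME", "MR", "GM")) {
    out[[m]] <- to_num_strict(raw[[m]], m) > 0
  }
  structure(out, class = c("evidence_table", class(out)))
}

#' Read / write a sample-design TSV
#'
#' Columns: `sample_id`, `group`, optionally `pair_id`.
#'
#' @param path Path.
#' @export
read_design <- function(path) {
  raw <- read_tsv_chr(path)
  i_s <- match_col(raw, "sample_id", path)
  i_g <- match_col(raw, "group", path)
  i_p <- match_col(raw, "pair_id", path, required = FALSE)
  sample_design(raw[[i_s]], raw[[i_g]],
                pair_id = if (!is.na(i_p)) raw[[i_p]] else NULL)
}

#' @rdname read_design
#' @param design A `sample_design` tibble.
#' @export
write_design <- function(design, path) {
  write_tsv_det(as_tibble(design), path)
}
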