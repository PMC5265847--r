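# Internal helpers shared across modules.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "omnilevel_format_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "omnilevel_validation_error", ...)
}

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = "omnilevel_argument_error", ...)
}

# Deterministic numeric formatting: data writers keep near-full precision so
# read(write(x)) is the identity for values of <= 15 significant digits;
# result writers use 6 significant digits so outputs diff cleanly.
fmt_num <- function(x, digits = 15L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    sprintf(paste0("%.", digits, "g"), v)
  }, character(1))
  out
}

# Write a data frame as a byte-deterministic TSV. Numeric columns are formatted
# with `digits` significant digits; everything else via as.character.
write_tsv_det <- function(df, path, digits = 15L) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col, digits = digits)
    else if (is.logical(col)) ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  })
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# Read a TSV fully as character (no NA interpretation) for strict validation.
read_tsv_chr <- function(path) {
  if (!file.exists(path)) {
    abort_argument(sprintf("file does not exist: %s", path))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE, show_col_types = FALSE)
}

# Convert a character column to numeric, reporting the 1-based file line of the
# first offending cell (header is line 1).
to_num_strict <- function(x, column, what = "value") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort_format(sprintf("non-numeric %s '%s' in column '%s' at line %d",
                         what, x[bad[1]], column, bad[1] + 1L))
  }
  out
}

`%||%` <- rlang::`%||%`
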