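#' Tidiers for screen results and pipeline results
#'
#' `tidy()` returns the per-feature table (one row per tested feature, sorted
#' by q then p); `glance()` returns a one-row summary per screen. For a full
#' pipeline result, `tidy()` stacks the five screens and `glance()` returns
#' one row per modality plus the nested level counts as attributes.
#'
#' @param x A `screen_result` or `omnilevel_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  df <- as_tibble(x)
  key <- if ("q" %in% names(df)) df$q else df$p
  df[order(!df$tested, key, df$p, df$feature_id, na.last = TRUE), ]
}

#' @rdname tidy.screen_result
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  df <- as_tibble(x)
  tibble(modality = attr(x, "modality"),
         n_features = nrow(df),
         n_tested = sum(df$tested),
         n_called = sum(df$called),
         min_p = suppressWarnings(min(df$p, na.rm = TRUE)),
         n_case = if (nrow(df)) max(df$n_case) else NA_integer_,
         n_comparison = if (nrow(df)) max(df$n_comparison) else NA_integer_)
}

#' @rdname tidy.screen_result
#' @method tidy omnilevel_result
#' @export
tidy.omnilevel_result <- function(x, ...) {
  bind_rows(lapply(x$screens, function(s) {
    df <- as_tibble(s)
    df[, intersect(c("modality", "feature_id", "effect", "p", "q",
                     "called", "tested"), names(df))]
  }))
}

#' @rdname tidy.screen_result
#' @method glance omnilevel_result
#' @export
glance.omnilevel_result <- function(x, ...) {
  bind_rows(lapply(x$screens, glance))
}
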