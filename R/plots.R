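#' Plot a modality screen as a volcano-style panel
#'
#' Effect size (log2 fold change, or the raw beta difference / odds ratio as
#' appropriate) against -log10 significance, with called features
#' highlighted. Rendering is descriptive only; nothing downstream depends on
#' the plot.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$tested & !is.na(df$effect), ]
  modality <- attr(object, "modality")
  sig <- if ("q" %in% names(df)) df$q else df$p
  sig_lab <- if ("q" %in% names(df)) "-log10 q" else "-log10 p"
  if (modality %in% c("GE", "CN", "MR", "GM")) {
    df$x <- log2(df$effect)
    x_lab <- if (modality == "GM") "log2 odds ratio" else "log2 fold change"
  } else {
    df$x <- df$effect
    x_lab <- "beta difference (normal - tumor)"
  }
  df$y <- -log10(pmax(sig, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = x_lab, y = sig_lab, colour = "called",
                  title = sprintf("%s screen", modality)) +
    ggplot2::theme_minimal()
}

#' Plot the evidence table as a gene-by-modality heatmap
#'
#' Mirrors the classic multi-omics evidence figure: genes at nested Level >=
#' `min_level` as rows, modalities as columns, filled where the gene is
#' hyperactivated in that analysis.
#'
#' @param object An `evidence_table`.
#' @param min_level Minimum nested level to include.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evidence_table
#' @export
autoplot.evidence_table <- function(object, min_level = 3L, ...) {
  df <- export_evidence_heatmap(object, min_level = min_level)
  long <- tidyr::pivot_longer(df, cols = c("GE", "CN", "ME", "MR", "GM"),
                              names_to = "modality", values_to = "evidence")
  long$modality <- factor(long$modality, levels = c("GE", "CN", "ME", "MR", "GM"))
  long$gene_id <- factor(long$gene_id, levels = rev(df$gene_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$modality, y = .data$gene_id,
                                     fill = factor(.data$evidence))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey40"),
                               labels = c(`0` = "no", `1` = "yes")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "hyperactivated") +
    ggplot2::theme_minimal()
}

#' Bar chart of nested level counts
#'
#' @param levels A `level_assignment`.
#' @return A ggplot object.
#' @export
plot_level_counts <- function(levels) {
  cnt <- level_counts(levels)
  ggplot2::ggplot(cnt, ggplot2::aes(x = factor(.data$level), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "evidence level (nested membership)", y = "genes") +
    ggplot2::theme_minimal()
}
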