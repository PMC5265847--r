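#' Run every screen and the evidence integration on an in-memory study
#'
#' Executes the five modality screens, maps the downregulated miRNAs to their
#' target genes, builds the evidence table, assigns nested evidence levels and
#' computes the default overlap counts. Deterministic given the study and
#' config.
#'
#' @param study A `synthetic_study` (from [generate_study()] or
#'   [read_study()]) or any list with the same fields.
#' @param config A [threshold_config()].
#' @return A list of class `omnilevel_result`: `screens` (named list of the
#'   five `screen_result`s), `mr_genes`, `evidence`, `levels`,
#'   `level_counts` (nested), `overlaps`, `config`.
#' @export
run_study <- function(study, config = threshold_config()) {
  config <- as_threshold_config(config)
  ge <- screen_expression(study$expression, study$design_expression, config)
  copies <- map_segments_to_genes(study$segments, study$gene_model,
                                  weighted = config$cn_weighted)
  cn <- screen_copy_number(copies, study$design_cnv, config)
  beta_a <- collapse_probes_to_genes(study$beta_a, study$probe_map_a)
  beta_b <- collapse_probes_to_genes(study$beta_b, study$probe_map_b)
  me <- screen_methylation(beta_a, beta_b, study$design_me_a,
                           study$design_me_b, config)
  mr <- screen_mirna(study$mirna, study$design_mirna, config)
  mr_genes <- map_mirna_targets(mr, study$target_map)
  case_calls <- study$maf[study$maf$sample_id %in% study$case_samples, ]
  case_mat <- build_mutation_matrix(case_calls, study$case_samples)
  bg_mat <- build_mutation_matrix(study$maf, study$background_samples)
  gm <- screen_mutations(case_mat, bg_mat, config)
  evidence <- build_evidence_table(ge, cn, me, mr_genes, gm)
  levels <- assign_levels(evidence)
  structure(list(
    screens = list(GE = ge, CN = cn, ME = me, MR = mr, GM = gm),
    mr_genes = mr_genes,
    evidence = evidence,
    levels = levels,
    level_counts = level_counts(levels),
    overlaps = overlap_counts(evidence),
    config = config), class = "omnilevel_result")
}

#' Run the pipeline on a study directory and write the result bundle
#'
#' Reads every input named in the study manifest (erroring up front with the
#' missing file names), runs [run_study()], optionally runs gene-set overlap
#' enrichment of the nested Level >= 2 list against a GMT collection (universe
#' = genes tested in the expression screen), and writes per-modality screen
#' tables, the evidence table, level assignments and counts, overlap counts,
#' the Level >= 3 heatmap table, and a run manifest (package version, config
#' hash and values, per-stage row counts). All writers are deterministic, so
#' rerunning on identical inputs is byte-identical.
#'
#' @param input_dir Study directory (see [write_study()]).
#' @param output_dir Output directory, created if needed.
#' @param config A [threshold_config()], a list of its fields, or a path to a
#'   YAML file holding them (optionally under a `thresholds:` key).
#' @param gmt Optional path to a GMT collection for the enrichment stage.
#' @param overwrite Allow writing into an existing result directory.
#' @return The `omnilevel_result`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir, config = threshold_config(),
                         gmt = NULL, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    y <- yaml::read_yaml(config)
    config <- do.call(threshold_config, y$thresholds %||% y)
  }
  config <- as_threshold_config(config)
  study <- read_study(input_dir)
  if (dir.exists(output_dir) &&
      file.exists(file.path(output_dir, "run_manifest.yaml")) && !overwrite) {
    abort_argument(sprintf("output directory '%s' already holds results; use overwrite = TRUE",
                           output_dir))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_study(study, config)
  p <- function(f) file.path(output_dir, f)
  for (m in names(res$screens)) {
    write_screen_result(res$screens[[m]], p(sprintf("screen_%s.tsv", tolower(m))))
  }
  write_tsv_det(tibble(gene_id = res$mr_genes), p("mr_target_genes.tsv"))
  write_evidence_table(res$evidence, p("evidence_table.tsv"))
  write_tsv_det(as_tibble(res$levels), p("levels.tsv"))
  write_tsv_det(res$level_counts, p("level_counts.tsv"))
  write_tsv_det(res$overlaps, p("overlap_counts.tsv"))
  export_evidence_heatmap(res$evidence, p("evidence_heatmap_level3.tsv"))
  if (!is.null(gmt)) {
    collection <- read_gmt(gmt)
    universe <- res$screens$GE$feature_id[res$screens$GE$tested]
    query <- level_members(res$levels, 2L)
    if (length(query) > 0) {
      enr <- enrich_overlap(query, collection, universe)
      write_tsv_det(enr, p("enrichment.tsv"), digits = 6L)
      res$enrichment <- enr
    }
  }
  manifest <- list(
    package = "omnilevel",
    version = as.character(packageVersion("omnilevel")),
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config),
    rows = lapply(res$screens, nrow),
    n_called = lapply(res$screens, function(s) sum(s$called)),
    n_evidence_genes = nrow(res$evidence),
    level_counts = setNames(as.list(res$level_counts$n),
                            paste0("L", res$level_counts$level)))
  yaml::write_yaml(manifest, p("run_manifest.yaml"))
  invisible(res)
}

#' @export
print.omnilevel_result <- function(x, ...) {
  cat("<omnilevel_result>\n")
  for (m in names(x$screens)) {
    s <- x$screens[[m]]
    cat(sprintf("  %s: %d/%d features called\n", m, sum(s$called), nrow(s)))
  }
  cat(sprintf("  evidence table: %d genes\n", nrow(x$evidence)))
  cat("  nested level counts:",
      paste(sprintf("L%d=%d", x$level_counts$level, x$level_counts$n),
            collapse = " "), "\n")
  invisible(x)
}
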