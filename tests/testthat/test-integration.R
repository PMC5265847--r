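test_that("evidence table is the union with per-modality flags", {
  ev <- build_evidence_table("a", "b", "c", "d", "e")
  expect_equal(nrow(ev), 5)
  expect_equal(sum(as.matrix(ev[, -1])), 5)
  expect_equal(nrow(build_evidence_table(character(0), character(0),
                                         character(0), character(0),
                                         character(0))), 0)
  ev2 <- build_evidence_table("g", "g", "g", "g", "g")
  expect_equal(nrow(ev2), 1)
  expect_true(all(as.matrix(ev2[, -1])))
})

test_that("level assignment gates on GE and counts supporting modalities", {
  ev <- build_evidence_table(ge = c("lad1", "solo", "full"),
                             cn = c("lad1", "ghost", "full"),
                             me = c("lad1", "ghost", "full"),
                             mr = "full", gm = "full")
  lv <- assign_levels(ev)
  # expression + copy gain + hypomethylation -> Level 3
  expect_equal(lv$level[lv$gene_id == "lad1"], 3L)
  expect_equal(lv$level[lv$gene_id == "solo"], 1L)
  expect_equal(lv$level[lv$gene_id == "full"], 5L)
  expect_false("ghost" %in% lv$gene_id)  # CN+ME without GE: no level
  expect_equal(level_counts(lv)$n, c(3L, 2L, 2L, 1L, 1L))
  expect_equal(level_counts(lv, nested = FALSE)$n, c(1L, 0L, 1L, 0L, 1L))
  expect_equal(level_members(lv, 3), c("full", "lad1"))
})

test_that("nested level counts are monotone and reconcile with exact counts", {
  set.seed(101)
  for (i in 1:20) {
    pool <- sprintf("g%03d", 1:60)
    pick <- function() sample(pool, sample(0:40, 1))
    ev <- build_evidence_table(pick(), pick(), pick(), pick(), pick())
    if (nrow(ev) == 0) next
    lv <- assign_levels(ev)
    cnt <- level_counts(lv)$n
    expect_true(all(diff(cnt) <= 0))
    exact <- level_counts(lv, nested = FALSE)$n
    expect_equal(rev(cumsum(rev(exact))), cnt)
    # sum over genes of supporting-modality counts reconciles with levels
    expect_equal(sum(lv$level - 1L),
                 sum((2:5 - 1) * exact[2:5]))
  }
})

test_that("overlap counts equal brute-force set intersections", {
  ev <- build_evidence_table(ge = c("a", "b", "c"), cn = c("b", "c"),
                             me = "c", mr = character(0), gm = character(0))
  oc <- overlap_counts(ev, combos = list(c("GE", "CN"), c("GE", "ME"),
                                         c("GE", "CN", "ME")))
  expect_equal(oc$n, c(2L, 1L, 1L))
  # disjoint and identical cases
  dis <- build_evidence_table("a", "b", "c", "d", "e")
  expect_true(all(overlap_counts(dis)$n == 0))
  idn <- build_evidence_table(c("x", "y"), c("x", "y"), c("x", "y"),
                              c("x", "y"), c("x", "y"))
  expect_true(all(overlap_counts(idn)$n == 2))
  set.seed(111)
  for (i in 1:15) {
    pool <- sprintf("g%02d", 1:30)
    sets <- replicate(5, sample(pool, sample(0:20, 1)), simplify = FALSE)
    ev_r <- build_evidence_table(sets[[1]], sets[[2]], sets[[3]], sets[[4]],
                                 sets[[5]])
    oc_r <- overlap_counts(ev_r, combos = list(c("GE", "CN"), c("CN", "ME", "GM")))
    expect_equal(oc_r$n[1], length(intersect(sets[[1]], sets[[2]])))
    expect_equal(oc_r$n[2],
                 length(Reduce(intersect, sets[c(2, 3, 5)])))
  }
  expect_error(overlap_counts(ev, combos = list(c("GE", "XX"))),
               class = "omnilevel_argument_error")
})

test_that("heatmap export keeps Level >= 3 genes with 0/1 cells and round-trips", {
  ev <- build_evidence_table(ge = c("a", "b", "c"), cn = c("a", "b"),
                             me = "a", mr = "b", gm = character(0))
  hm <- export_evidence_heatmap(ev)
  expect_equal(hm$gene_id, c("a", "b"))
  expect_equal(hm$level, c(3L, 3L))
  expect_equal(unlist(hm[hm$gene_id == "a", c("GE", "CN", "ME", "MR", "GM")],
                      use.names = FALSE), c(1L, 1L, 1L, 0L, 0L))
  none <- build_evidence_table("a", "b", character(0), character(0),
                               character(0))
  expect_equal(nrow(export_evidence_heatmap(none)), 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_evidence_heatmap(ev, path)
  back <- read_tsv_lines <- readLines(path)
  expect_equal(back[1], "gene_id\tlevel\tGE\tCN\tME\tMR\tGM")
  expect_equal(back[2], "a\t3\t1\t1\t1\t0\t0")
})

test_that("mutation matrix collapses duplicates and honors the class filter", {
  calls <- tibble::tibble(
    gene_id = c("TP53", "TP53", "TTN", "MUC4", "MUC4"),
    sample_id = c("S1", "S1", "S2", "S3", "S9"),
    variant_classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Silent", "Missense_Mutation", "Missense_Mutation"))
  m <- suppressMessages(build_mutation_matrix(calls, c("S1", "S2", "S3")))
  expect_equal(m["TP53", "S1"], 1L)            # at least 1, not 2
  expect_false("TTN" %in% rownames(m))         # Silent-only gene filtered
  expect_equal(dim(m), c(2L, 3L))              # S9 call dropped
  m_all <- suppressMessages(build_mutation_matrix(calls, c("S1", "S2", "S3"),
                                                  classification_filter = "all"))
  expect_equal(m_all["TTN", "S2"], 1L)
  m_only <- suppressMessages(build_mutation_matrix(
    calls, c("S1", "S2", "S3"), classification_filter = "Nonsense_Mutation"))
  expect_equal(rownames(m_only), "TP53")
  empty <- build_mutation_matrix(calls[0, ], c("S1", "S2"))
  expect_equal(nrow(empty), 0)
})

test_that("mutation screen reproduces the TP53-style enrichment", {
  # 78% of 54 cases vs 31% of 992 background: OR ~ 7.7, p far below 0.05
  case <- matrix(c(rep(1L, 42), rep(0L, 12)), nrow = 1,
                 dimnames = list("TP53", sprintf("C%02d", 1:54)))
  bg <- matrix(c(rep(1L, 308), rep(0L, 684)), nrow = 1,
               dimnames = list("TP53", sprintf("B%03d", 1:992)))
  res <- screen_mutations(structure(case, class = "mutation_matrix"),
                          structure(bg, class = "mutation_matrix"))
  expect_true(res$called)
  expect_lt(abs(res$effect - 7.7) / 7.7, 0.02)
  expect_lt(res$p, 1e-10)
  expect_false("q" %in% names(res))  # raw p by design

  # zero case mutations -> OR <= 1 branch, never called
  case0 <- matrix(0L, 1, 10, dimnames = list("g", sprintf("C%d", 1:10)))
  bg1 <- matrix(c(rep(1L, 5), rep(0L, 95)), 1,
                dimnames = list("g", sprintf("B%d", 1:100)))
  res0 <- screen_mutations(structure(case0, class = "mutation_matrix"),
                           structure(bg1, class = "mutation_matrix"))
  expect_false(res0$called)

  # 5/10 cases vs 5/100 background is comfortably enriched
  case5 <- matrix(c(rep(1L, 5), rep(0L, 5)), 1,
                  dimnames = list("g", sprintf("C%d", 1:10)))
  res5 <- screen_mutations(structure(case5, class = "mutation_matrix"),
                           structure(bg1, class = "mutation_matrix"))
  expect_true(res5$called)
  expect_equal(res5$p, oracle_fisher_p(5, 5, 5, 95), tolerance = 1e-9)
})

test_that("gene-set enrichment matches the hypergeometric kernel", {
  collection <- list(hit = sprintf("g%02d", 1:5),
                     other = sprintf("g%02d", 10:14),
                     other_copy = sprintf("g%02d", 10:14))
  universe <- sprintf("g%02d", 1:20)
  enr <- enrich_overlap(sprintf("g%02d", 1:5), collection, universe,
                        fdr_cutoff = 1e-3)
  hit <- enr[enr$set_name == "hit", ]
  expect_equal(hit$p, 1 / choose(20, 5))
  expect_true(hit$significant)
  expect_equal(enr$p[enr$set_name == "other"],
               enr$p[enr$set_name == "other_copy"])
  # disjoint query -> all p = 1
  enr2 <- enrich_overlap(sprintf("g%02d", 15:20),
                         list(s = sprintf("g%02d", 1:5)), universe)
  expect_equal(enr2$p, 1)
  # genes outside the universe never change a set's p
  aug <- list(hit = c(collection$hit, "not_in_universe_1", "zzz"))
  enr3 <- enrich_overlap(sprintf("g%02d", 1:5), aug, universe)
  expect_equal(enr3$p[1], hit$p)
  # p monotone non-increasing in overlap at fixed sizes
  ps <- vapply(0:5, function(k) hypergeom_overlap_p(50, 10, 8, k), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(enrich_overlap(character(0), collection, universe),
               class = "omnilevel_argument_error")
  expect_warning(enrich_overlap(c("g01", "absent"), collection, universe),
                 "outside the universe")
})
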