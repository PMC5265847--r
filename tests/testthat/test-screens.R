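# Constructed fixtures with exactly one planted feature, plus threshold-logic
# and invariance properties shared by all screens.

make_paired_fixture <- function(n_pairs = 20, n_genes = 5, planted_fold = 4,
                                seed = 1) {
  set.seed(seed)
  t_ids <- sprintf("T%02d", 1:n_pairs); n_ids <- sprintf("N%02d", 1:n_pairs)
  base <- matrix(rep(10 * (1:n_genes), 2 * n_pairs), n_genes)
  mat <- base + matrix(runif(n_genes * 2 * n_pairs, -0.5, 0.5), n_genes)
  dimnames(mat) <- list(sprintf("g%d", 1:n_genes), c(t_ids, n_ids))
  mat["g1", t_ids] <- mat["g1", n_ids] * planted_fold
  design <- sample_design(c(t_ids, n_ids),
                          rep(c("tumor", "normal"), each = n_pairs),
                          pair_id = rep(sprintf("P%02d", 1:n_pairs), 2))
  list(mat = mat, design = design)
}

test_that("expression screen calls exactly the planted gene", {
  fx <- make_paired_fixture()
  res <- screen_expression(omics_matrix(fx$mat, "expression"), fx$design)
  expect_equal(called_features(res), "g1")
  g1 <- res[res$feature_id == "g1", ]
  expect_gt(g1$effect, 3.5)
  # perfectly separated pairs: signed-rank p = 2 / 2^20 before FDR
  expect_equal(g1$p, 2 / 2^20, tolerance = 1e-9)
  expect_true(all(res$tested))
})

test_that("screens report empty inputs and threshold conjunctions correctly", {
  fx <- make_paired_fixture()
  empty <- omics_matrix(fx$mat[0, , drop = FALSE], "expression")
  res <- screen_expression(empty, fx$design)
  expect_equal(nrow(res), 0)
  # large fold but relaxed significance threshold not met -> not called
  small <- make_paired_fixture(n_pairs = 4)
  res2 <- screen_expression(omics_matrix(small$mat, "expression"), small$design,
                            threshold_config(ge_fdr = 0.01))
  g1 <- res2[res2$feature_id == "g1", ]
  expect_gt(g1$effect, 2)
  expect_gt(g1$q, 0.01)  # only 4 pairs: min possible p = 2/16 -> q above cut
  expect_false(g1$called)
  expect_error(screen_expression(omics_matrix(fx$mat, "expression"),
                                 sample_design("T01", "tumor")),
               class = "omnilevel_argument_error")
})

test_that("copy-number screen applies the 1.2-fold rule on linear copies", {
  fx <- make_paired_fixture()
  mat <- fx$mat
  mat[] <- 2 + matrix(runif(length(mat), -0.05, 0.05), nrow(mat))
  t_ids <- grep("^T", colnames(mat), value = TRUE)
  mat["g1", t_ids] <- 3 + runif(length(t_ids), -0.05, 0.05)  # fold 1.5
  mat["g2", t_ids] <- mat["g2", t_ids] * 1.1                 # fold 1.1
  res <- screen_copy_number(omics_matrix(mat, "copy_number"), fx$design)
  expect_equal(called_features(res), "g1")
  g2 <- res[res$feature_id == "g2", ]
  expect_lt(g2$q, 0.05)     # significant...
  expect_false(g2$called)   # ...but below the 1.2-fold floor
  # all-neutral imputed copies -> constant differences -> untested
  flat <- matrix(2, 2, ncol(mat), dimnames = list(c("a", "b"), colnames(mat)))
  res_flat <- screen_copy_number(omics_matrix(flat, "copy_number"), fx$design)
  expect_false(any(res_flat$tested))
  expect_false(any(res_flat$called))
})

test_that("probe collapse averages, passes singletons, propagates missing", {
  mat <- matrix(c(0.2, 0.4, 0.6, NA, NA, 0.8), nrow = 3,
                dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  pm <- tibble::tibble(probe_id = c("p1", "p2", "p3", "px"),
                       gene_id = c("gA", "gA", "gB", "gC"))
  g <- suppressMessages(collapse_probes_to_genes(omics_matrix(mat, "beta"), pm))
  v <- om_values(g)
  expect_equal(v["gA", "s1"], 0.3)       # mean of two probes
  expect_equal(v["gB", "s1"], 0.6)       # singleton identity
  expect_equal(v["gA", "s2"], NA_real_)  # all probes missing
  expect_equal(v["gB", "s2"], 0.8)
})

make_me_fixture <- function(delta_a = 0.2, delta_b = 0.2, n = 20, seed = 2) {
  set.seed(seed)
  build <- function(delta) {
    t_ids <- sprintf("T%02d", 1:n); n_ids <- sprintf("N%02d", 1:n)
    mat <- matrix(0.5, 3, 2 * n, dimnames = list(c("g1", "g2", "g3"),
                                                 c(t_ids, n_ids)))
    mat <- mat + matrix(runif(length(mat), -0.01, 0.01), nrow(mat))
    mat["g1", t_ids] <- mat["g1", t_ids] - delta
    list(beta = omics_matrix(mat, "beta"),
         design = sample_design(c(t_ids, n_ids),
                                rep(c("tumor", "normal"), each = n)))
  }
  list(a = build(delta_a), b = build(delta_b))
}

test_that("methylation screen requires both platforms to pass", {
  fx <- make_me_fixture()
  res <- screen_methylation(fx$a$beta, fx$b$beta, fx$a$design, fx$b$design)
  expect_equal(called_features(res), "g1")
  g1 <- res[res$feature_id == "g1", ]
  expect_gt(g1$delta_a, 0.15); expect_gt(g1$delta_b, 0.15)

  # below the 5% floor on platform A -> never called
  fx2 <- make_me_fixture(delta_a = 0.04)
  res2 <- screen_methylation(fx2$a$beta, fx2$b$beta, fx2$a$design, fx2$b$design)
  expect_equal(called_features(res2), character(0))

  # significant on one platform only -> intersection rule blocks the call
  fx3 <- make_me_fixture(delta_a = 0.2, delta_b = 0)
  res3 <- screen_methylation(fx3$a$beta, fx3$b$beta, fx3$a$design, fx3$b$design)
  expect_equal(called_features(res3), character(0))
  g1_3 <- res3[res3$feature_id == "g1", ]
  expect_lt(g1_3$q_a, 0.05)

  expect_error(
    screen_methylation(fx$a$beta, fx$b$beta,
                       sample_design(om_samples(fx$a$beta),
                                     rep("tumor", 2 * 20)),
                       fx$b$design),
    class = "omnilevel_argument_error")
})

test_that("miRNA screen calls planted downregulation and maps targets", {
  set.seed(3)
  n_t <- 20; n_n <- 40
  t_ids <- sprintf("T%02d", 1:n_t); n_ids <- sprintf("N%02d", 1:n_n)
  mat <- 2^(8 + matrix(rnorm(4 * (n_t + n_n), 0, 0.3), 4))
  dimnames(mat) <- list(sprintf("miR-%d", 1:4), c(t_ids, n_ids))
  mat["miR-1", t_ids] <- mat["miR-1", t_ids] / 4
  mat["miR-3", ] <- 7  # constant -> degenerate p = 1
  design <- sample_design(c(t_ids, n_ids),
                          rep(c("tumor", "normal"), c(n_t, n_n)))
  res <- screen_mirna(omics_matrix(mat, "mirna"), design)
  expect_equal(called_features(res), "miR-1")
  m3 <- res[res$feature_id == "miR-3", ]
  expect_equal(m3$p, 1)
  expect_true(m3$tested)
  expect_false(m3$called)

  tm <- tibble::tibble(mirna_id = c("miR-1", "miR-1", "miR-9", "miR-9"),
                       gene_id = c("g1", "g2", "g2", "g3"))
  expect_equal(map_mirna_targets(res, tm), c("g1", "g2"))
  expect_equal(map_mirna_targets(character(0), tm), character(0))
  expect_equal(map_mirna_targets(c("miR-1", "miR-9"), tm), c("g1", "g2", "g3"))
  expect_warning(out <- map_mirna_targets(c("miR-1", "miR-404"), tm),
                 "absent from the target map")
  expect_equal(out, c("g1", "g2"))
})

test_that("tightening any threshold never adds a called feature", {
  study <- generate_study(tiny_config(17))
  base_cfg <- threshold_config()
  res <- suppressMessages(run_study(study, base_cfg))
  tighter <- list(threshold_config(ge_fold = 3), threshold_config(ge_fdr = 0.01),
                  threshold_config(cn_fold = 1.4), threshold_config(me_delta_beta = 0.1),
                  threshold_config(mr_fold = 3), threshold_config(gm_p = 0.01))
  for (cfg in tighter) {
    res_t <- suppressMessages(run_study(study, cfg))
    for (m in names(res$screens)) {
      expect_true(all(called_features(res_t$screens[[m]]) %in%
                        called_features(res$screens[[m]])),
                  info = m)
    }
  }
})

test_that("screens are deterministic and row-permutation equivariant", {
  fx <- make_paired_fixture(n_genes = 8)
  m <- omics_matrix(fx$mat, "expression")
  r1 <- screen_expression(m, fx$design)
  r2 <- screen_expression(m, fx$design)
  expect_identical(r1, r2)
  perm <- sample(nrow(fx$mat))
  r3 <- screen_expression(omics_matrix(fx$mat[perm, ], "expression"), fx$design)
  expect_equal(as.data.frame(r3[match(r1$feature_id, r3$feature_id), ]),
               as.data.frame(r1), ignore_attr = TRUE)
})
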