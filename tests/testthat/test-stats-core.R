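test_that("signed-rank test matches frozen exact values and conventions", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 2 / 32)
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)
  out <- wilcoxon_signed_rank(rep(0, 6))
  expect_equal(out$p_value, 1)
  expect_true(out$degenerate)
  expect_error(wilcoxon_signed_rank(numeric(0)), class = "omnilevel_argument_error")
})

test_that("rank-sum test matches frozen exact values and conventions", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 2 / choose(6, 3))
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 2 / 6)
  expect_equal(wilcoxon_rank_sum(5, 5)$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), class = "omnilevel_argument_error")
})

test_that("two-sample t matches the closed-form Welch statistic", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  out <- two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(out$statistic, oracle_welch_t(c(1, 2, 3, 4), c(3, 4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(round(out$statistic, 3), -2.191)
  degen <- two_sample_t(c(0, 0), c(1, 1))
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)
  degen2 <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(degen2$p_value, 1)
  expect_true(degen2$degenerate)
  expect_error(two_sample_t(1, c(1, 2)), class = "omnilevel_argument_error")
})

test_that("t test agrees with stats::t.test on regular inputs", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    mine <- two_sample_t(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    mine_s <- two_sample_t(x, y, var_equal = TRUE)
    ref_s <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine_s$p_value, ref_s$p.value, tolerance = 1e-10)
  }
})

test_that("fisher exact matches frozen values, symmetry, and fisher.test p", {
  tp53 <- fisher_exact_2x2(42, 12, 308, 684)
  expect_equal(tp53$odds_ratio, 42 * 684 / (12 * 308))
  expect_lt(abs(tp53$odds_ratio - 7.7) / 7.7, 0.02)
  expect_lt(tp53$p_value, 1e-10)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  ext <- fisher_exact_2x2(3, 0, 0, 3)
  expect_equal(ext$odds_ratio, Inf)
  expect_equal(ext$p_value, 2 / choose(6, 3))
  expect_error(fisher_exact_2x2(0, 0, 1, 1), class = "omnilevel_argument_error")
  # row/column swap invariance of p; OR inversion on row swap
  set.seed(21)
  for (i in 1:25) {
    t <- sample(0:12, 4, replace = TRUE)
    if (t[1] + t[2] == 0 || t[3] + t[4] == 0) next
    p1 <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    if (t[1] + t[3] == 0 || t[2] + t[4] == 0) next
    p2 <- fisher_exact_2x2(t[1], t[3], t[2], t[4])  # transpose
    expect_equal(p1$p_value, p2$p_value, tolerance = 1e-9)
    p3 <- fisher_exact_2x2(t[3], t[4], t[1], t[2])  # swap rows
    if (is.finite(p1$odds_ratio) && p1$odds_ratio > 0) {
      expect_equal(p3$odds_ratio, 1 / p1$odds_ratio, tolerance = 1e-12)
    }
    ref <- fisher.test(matrix(t, 2, byrow = TRUE))
    expect_equal(p1$p_value, ref$p.value, tolerance = 1e-7)
  }
})

test_that("bh_fdr matches the step-up formula, handles NA, validates input", {
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  # NA excluded from m: remaining entries adjusted as if alone
  expect_equal(bh_fdr(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "omnilevel_argument_error")
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("bh_fdr output is monotone in p-rank, bounded, rank-preserving", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(25)
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    # re-adjusting never reorders: q-ranks are stable under re-application
    q2 <- bh_fdr(q)
    expect_true(all(diff(q2[o]) >= -1e-12))
    expect_true(all(q2 >= q))
  }
})

test_that("hypergeometric tail matches closed forms", {
  expect_equal(hypergeom_overlap_p(20, 5, 5, 5), 1 / choose(20, 5))
  expect_equal(hypergeom_overlap_p(10, 5, 2, 0), 1)
  expect_equal(hypergeom_overlap_p(10, 5, 2, 1), 7 / 9)
  expect_error(hypergeom_overlap_p(10, 5, 2, 3), class = "omnilevel_argument_error")
  expect_error(hypergeom_overlap_p(10, 12, 2, 1), class = "omnilevel_argument_error")
})

test_that("exact tests equal enumeration oracles on random small instances", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    d <- rand_small_diffs(n)
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank(d),
                 tolerance = 1e-9, info = paste(d, collapse = ","))
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    x <- sample(1:6, nx, replace = TRUE); y <- sample(1:6, ny, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_rank_sum(x, y),
                 tolerance = 1e-9)
    t <- sample(0:8, 4, replace = TRUE)
    if (t[1] + t[2] > 0 && t[3] + t[4] > 0) {
      expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4])$p_value,
                   oracle_fisher_p(t[1], t[2], t[3], t[4]), tolerance = 1e-9)
    }
  }
})

test_that("signed-rank exact path agrees with wilcox.test when tie-free", {
  set.seed(61)
  for (i in 1:20) {
    d <- round(rnorm(sample(4:15, 1)), 4)
    ref <- suppressWarnings(wilcox.test(d, exact = TRUE))
    expect_equal(wilcoxon_signed_rank(d)$p_value, ref$p.value, tolerance = 1e-9)
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- round(rnorm(n1), 4); y <- round(rnorm(n2), 4)
    ref2 <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref2$p.value, tolerance = 1e-9)
  }
})

test_that("exact and approximate paths agree at the size boundary", {
  # kernel contract: both paths within 10% relative p at boundary sizes, in
  # the moderate-p regime where screening decisions have any ambiguity; the
  # far tail is compared on the calls it implies, not relative error
  set.seed(71)
  checked <- 0
  for (i in 1:60) {
    d <- rnorm(26, mean = runif(1, 0, 0.3))
    p_apx <- wilcoxon_signed_rank(d)$p_value  # n 26 -> approximation
    p_ex <- wilcoxon_signed_rank(d, exact_max = 30)$p_value
    if (p_ex >= 0.05) {
      expect_lt(abs(p_apx - p_ex) / p_ex, 0.10)
      checked <- checked + 1
    } else {
      expect_lt(p_apx, 0.05)  # both sides of the cut agree on the call
    }
    x <- rnorm(10); y <- rnorm(10, runif(1, 0, 0.5))
    p_apx2 <- wilcoxon_rank_sum(x, y, exact_max_total = 10)$p_value
    p_ex2 <- wilcoxon_rank_sum(x, y)$p_value
    if (p_ex2 >= 0.05) {
      expect_lt(abs(p_apx2 - p_ex2) / p_ex2, 0.10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 40)
})

test_that("p-values are approximately uniform under the global null", {
  set.seed(81)
  n_rep <- 4000
  p_sr <- vapply(seq_len(n_rep),
                 function(i) wilcoxon_signed_rank(rnorm(30))$p_value, numeric(1))
  p_rs <- vapply(seq_len(n_rep),
                 function(i) wilcoxon_rank_sum(rnorm(15), rnorm(15))$p_value,
                 numeric(1))
  p_t <- vapply(seq_len(n_rep),
                function(i) two_sample_t(rnorm(10), rnorm(10))$p_value, numeric(1))
  ks <- function(p) max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks(p_sr), 0.05)
  expect_lt(ks(p_rs), 0.05)
  expect_lt(ks(p_t), 0.05)
})
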