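# Independent brute-force oracles. These deliberately share no code with the
# package: sign/labeling enumeration over explicit grids, closed-form
# hypergeometric sums, the textbook BH step-up, and a per-base interval walk.

two_sided <- function(stats, w, tol = 1e-9) {
  p_le <- mean(stats <= w + tol)
  p_ge <- mean(stats >= w - tol)
  min(1, 2 * min(p_le, p_ge))
}

oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% r)
  w <- sum(r[d > 0])
  two_sided(stats, w)
}

oracle_rank_sum <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  labelings <- utils::combn(length(r), n)
  stats <- apply(labelings, 2, function(idx) sum(r[idx]))
  w <- sum(r[seq_len(n)])
  two_sided(stats, w)
}

oracle_fisher_p <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  support <- max(0, col1 - (c + d)):min(row1, col1)
  point <- function(x) {
    choose(col1, x) * choose(n - col1, row1 - x) / choose(n, row1)
  }
  probs <- vapply(support, point, numeric(1))
  p_obs <- point(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
}

# Per-base copy-number oracle: for every base of every gene, the linear copy
# of the (unique, non-overlapping) segment covering it in that sample; gene
# value = mean over covered bases (length weighting emerges from the per-base
# average), or the neutral value when no base is covered.
oracle_gene_copy <- function(segments, genes, sample, neutral = 2) {
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    segs <- segments[segments$sample_id == sample & segments$chrom == g$chrom, ]
    vals <- c()
    for (pos in seq(g$start, g$end)) {
      hit <- which(segs$start <= pos & segs$end >= pos)
      if (length(hit) == 1) vals <- c(vals, 2 * 2^segs$seg_value[hit])
    }
    if (length(vals) == 0) neutral else mean(vals)
  }, numeric(1))
}

# Small random inputs shared by property tests
rand_small_diffs <- function(n, allow_ties = TRUE) {
  pool <- if (allow_ties) c(-3:-1, 1:3) else NULL
  if (allow_ties) sample(pool, n, replace = TRUE)
  else round(rnorm(n), 3)
}

rand_segments <- function(sample_ids, chroms, genome_len, max_segs = 6) {
  rows <- list()
  for (s in sample_ids) {
    for (ch in chroms) {
      n_seg <- sample.int(max_segs, 1)
      cuts <- sort(sample.int(genome_len, 2 * n_seg))
      for (k in seq_len(n_seg)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = s, chrom = ch,
          start = cuts[2 * k - 1], end = cuts[2 * k],
          seg_value = round(stats::runif(1, -2, 2), 3))
      }
    }
  }
  segs <- dplyr::bind_rows(rows)
  # enforce non-overlap within sample/chrom: drop rows touching a predecessor
  segs <- segs |>
    dplyr::group_by(sample_id, chrom) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() == 1 | start > dplyr::lag(cummax(end))) |>
    dplyr::ungroup()
  segs
}

rand_gene_model <- function(n_genes, chroms, genome_len) {
  rows <- lapply(seq_len(n_genes), function(i) {
    a <- sample.int(genome_len - 10, 1)
    tibble::tibble(gene_id = sprintf("g%02d", i),
                   chrom = sample(chroms, 1),
                   start = a, end = a + sample.int(200, 1))
  })
  dplyr::bind_rows(rows)
}

# Tiny deterministic study for fast end-to-end tests
tiny_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_genes = 120, genes_per_chrom = 60,
                   n_pairs_expression = 12, n_pairs_cnv = 12,
                   me_a_tumor = 8, me_a_normal = 8,
                   me_b_tumor = 7, me_b_normal = 9,
                   mirna_tumor = 10, mirna_normal = 15,
                   n_case_maf = 15, n_background_maf = 80, n_mirnas = 30,
                   n_planted_triple = 4, n_planted_ge_cn = 4,
                   n_planted_ge_me = 4, n_planted_ge_only = 4,
                   n_planted_cn_only = 6, n_planted_me_only = 6,
                   n_planted_mirna = 3, targets_per_mirna = 4,
                   n_decoy_mirnas = 5, n_planted_gm = 8)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
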