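#' Statistical kernel
#'
#' Self-contained tests used by the modality screens: exact/approximate
#' Wilcoxon signed-rank and rank-sum tests, Welch/Student two-sample t,
#' Fisher's exact test on a 2x2 table, Benjamini-Hochberg q-values, and the
#' hypergeometric upper-tail overlap probability.
#'
#' All tests are two-sided and return a one-row tibble with columns
#' `statistic`, `p_value`, `method` and `degenerate`. Degenerate inputs
#' (all-zero differences, zero-variance groups) are flagged rather than raised,
#' so genome-wide screens never abort on constant features.
#'
#' @name stats-kernel
NULL

test_outcome <- function(statistic, p_value, method, degenerate = FALSE) {
  tibble(statistic = statistic, p_value = p_value,
         method = method, degenerate = degenerate)
}

# Exact null distribution of the signed-rank statistic W+ = sum of ranks with
# positive sign, over independent uniform signs. Ranks may be tied (average
# ranks are multiples of 1/2), so work on doubled ranks. Returns probabilities
# over doubled-sum support 0..sum(r2).
signed_rank_null <- function(r2) {
  f <- numeric(sum(r2) + 1L)
  f[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(length(f) - r)])
    f <- f + shifted
  }
  f / 2^length(r2)
}

two_sided_from_dist <- function(dist, w2) {
  # dist over doubled statistic 0..length(dist)-1; observed doubled value w2
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):length(dist)])
  min(1, 2 * min(p_le, p_ge))
}

wsr_core <- function(d, exact_max = 25L) {
  d <- d[!is.na(d)]
  if (length(d) == 0L) abort_argument("signed-rank test needs at least one difference")
  dz <- d[d != 0]
  if (length(dz) == 0L) {
    return(list(statistic = 0, p_value = 1,
                method = "signed-rank degenerate (all differences zero)",
                degenerate = TRUE))
  }
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  n <- length(dz)
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    dist <- signed_rank_null(r2)
    p <- two_sided_from_dist(dist, as.integer(round(2 * W)))
    list(statistic = W, p_value = p,
         method = "signed-rank exact (sign enumeration)", degenerate = FALSE)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- max(0, abs(W - mu) - 0.5) / sigma
    list(statistic = W, p_value = min(1, 2 * pnorm(-z)),
         method = "signed-rank normal approximation (continuity-corrected)",
         degenerate = FALSE)
  }
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test of symmetry about zero. Zero differences are dropped before
#' ranking (the classic Wilcoxon convention). The exact null distribution is
#' obtained by sign enumeration (via a generating-function convolution that
#' handles tied ranks) when the number of non-zero differences is at most
#' `exact_max`; otherwise a continuity-corrected normal approximation with
#' tie-aware variance is used. All-zero input returns p = 1 with
#' `degenerate = TRUE`.
#'
#' @param differences Numeric vector of paired differences (NAs dropped).
#' @param exact_max Largest number of non-zero differences for which the exact
#'   enumeration is used.
#' @return A one-row tibble: `statistic` (W+, the positive-rank sum),
#'   `p_value`, `method`, `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))  # exact p = 0.0625
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25L) {
  if (!is.numeric(differences)) abort_argument("`differences` must be numeric")
  out <- wsr_core(differences, exact_max = exact_max)
  test_outcome(out$statistic, out$p_value, out$method, out$degenerate)
}

# Exact null distribution of the rank-sum of group x: counts of k-subsets of
# the (doubled, possibly tied) ranks by subset sum. Matrix DP over
# (subset size, doubled sum).
rank_sum_null <- function(r2, n) {
  S <- sum(r2)
  f <- matrix(0, nrow = n + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    for (k in seq(min(n, 1e9), 1L)) {
      f[k + 1L, (r + 1L):(S + 1L)] <- f[k + 1L, (r + 1L):(S + 1L)] +
        f[k, 1L:(S - r + 1L)]
    }
  }
  f[n + 1L, ] / choose(length(r2), n)
}

wrs_core <- function(x, y, exact_max_total = 20L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort_argument("rank-sum test needs both groups non-empty")
  }
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  if (N <= exact_max_total) {
    r2 <- as.integer(round(2 * r))
    dist <- rank_sum_null(r2, n)
    p <- two_sided_from_dist(dist, as.integer(round(2 * W)))
    list(statistic = W, p_value = p,
         method = "rank-sum exact (labeling enumeration)", degenerate = FALSE)
  } else {
    mu <- n * (N + 1) / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- n * m / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      return(list(statistic = W, p_value = 1,
                  method = "rank-sum degenerate (all values tied)",
                  degenerate = TRUE))
    }
    z <- max(0, abs(W - mu) - 0.5) / sqrt(v)
    list(statistic = W, p_value = min(1, 2 * pnorm(-z)),
         method = "rank-sum normal approximation (tie-corrected)",
         degenerate = FALSE)
  }
}

#' Wilcoxon rank-sum test for two unpaired groups
#'
#' Two-sided test on the rank sum of `x` within the pooled sample. Exact by
#' enumeration of group labelings (ties handled exactly) when the combined
#' sample size is at most `exact_max_total`; otherwise a tie-corrected,
#' continuity-corrected normal approximation.
#'
#' @param x,y Numeric vectors (NAs dropped); both must be non-empty.
#' @param exact_max_total Largest combined sample size for the exact path.
#' @return A one-row tibble: `statistic` (rank sum of `x`), `p_value`,
#'   `method`, `degenerate`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_total = 20L) {
  if (!is.numeric(x) || !is.numeric(y)) abort_argument("`x` and `y` must be numeric")
  out <- wrs_core(x, y, exact_max_total = exact_max_total)
  test_outcome(out$statistic, out$p_value, out$method, out$degenerate)
}

tt_core <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort_argument("t test needs at least two values per group")
  }
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) {
      return(list(statistic = 0, p_value = 1,
                  method = "t degenerate (zero variance, equal means)",
                  degenerate = TRUE))
    }
    return(list(statistic = sign(mx - my) * Inf, p_value = 0,
                method = "t degenerate (zero variance, unequal means)",
                degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  list(statistic = t, p_value = min(1, 2 * pt(-abs(t), df)),
       method = if (var_equal) "two-sample t (pooled variance)" else "two-sample t (Welch)",
       degenerate = FALSE)
}

#' Two-sample t test
#'
#' Two-sided two-sample t test, Welch form by default (unequal variances,
#' Welch-Satterthwaite degrees of freedom); `var_equal = TRUE` gives the
#' pooled-variance Student form. Both groups zero-variance returns a flagged
#' degenerate p of 1 (equal means) or 0 (unequal means).
#'
#' @param x,y Numeric vectors with at least two non-missing values each.
#' @param var_equal Use the pooled-variance form instead of Welch.
#' @return A one-row tibble: `statistic`, `p_value`, `method`, `degenerate`.
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  if (!is.numeric(x) || !is.numeric(y)) abort_argument("`x` and `y` must be numeric")
  out <- tt_core(x, y, var_equal = var_equal)
  test_outcome(out$statistic, out$p_value, out$method, out$degenerate)
}

fisher_core <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d)))) {
    abort_argument("2x2 table entries must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0) {
    abort_argument("both rows of the 2x2 table must have positive totals")
  }
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * c)
  }
  row1 <- a + b; col1 <- a + c; N <- a + b + c + d
  support <- max(0L, col1 - (c + d)):min(row1, col1)
  probs <- dhyper(support, col1, N - col1, row1)
  p_obs <- dhyper(a, col1, N - col1, row1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Rows are (case, comparison), columns are (event, no event). The effect is
#' the sample odds ratio `a*d / (b*c)` (+Inf when `b*c` is zero and `a*d`
#' positive). The two-sided p-value uses the point-probability rule: the sum of
#' hypergeometric outcome probabilities no larger than that of the observed
#' table.
#'
#' @param a,b Case row: event / no-event counts.
#' @param c,d Comparison row: event / no-event counts.
#' @return A one-row tibble: `odds_ratio`, `p_value`, `method`.
#' @examples
#' fisher_exact_2x2(42, 12, 308, 684)  # odds ratio ~ 7.8
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  out <- fisher_core(a, b, c, d)
  tibble(odds_ratio = out$odds_ratio, p_value = out$p_value,
         method = "Fisher exact (two-sided, point-probability rule)")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. Missing entries propagate as missing and are
#' excluded from the number of tests m. Output preserves input order and
#' satisfies q >= p elementwise.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) abort_argument("`p_values` must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort_argument("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Hypergeometric upper-tail overlap probability
#'
#' P(X >= overlap) where X is the overlap between a fixed set of `set_size`
#' genes and a random query of `query_size` genes drawn without replacement
#' from a universe of `universe_size` genes.
#'
#' @param universe_size,set_size,query_size,overlap Non-negative integers with
#'   `set_size`, `query_size` at most `universe_size` and `overlap` at most
#'   `min(set_size, query_size)`.
#' @return The upper-tail probability.
#' @export
hypergeom_overlap_p <- function(universe_size, set_size, query_size, overlap) {
  args <- c(universe_size, set_size, query_size, overlap)
  if (any(args < 0) || any(args != round(args))) {
    abort_argument("all sizes must be non-negative integers")
  }
  if (set_size > universe_size || query_size > universe_size) {
    abort_argument("set and query sizes cannot exceed the universe size")
  }
  if (overlap > min(set_size, query_size)) {
    abort_argument("overlap cannot exceed min(set_size, query_size)")
  }
  phyper(overlap - 1, set_size, universe_size - set_size, query_size,
         lower.tail = FALSE)
}
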