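# Independent oracles and generators used across the suite.

# Exact rational Cohen's kappa for an integer table: all quantities stay
# integral (exact in doubles far below 2^53), independent of the
# package's floating-point path.
kappa_rational <- function(tab) {
  n <- sum(tab)
  trace <- sum(diag(tab))
  rc <- sum(rowSums(tab) * colSums(tab))
  (n * trace - rc) / (n^2 - rc)
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# summation under the probability-mass criterion (same tie tolerance as
# the implementation, but computed from dhyper, not enumeration).
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ])          # row-1 margin
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1])          # column-1 margin
  xs <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random 2x2 table with total at most n_max and non-degenerate margins.
rand_2x2 <- function(n_max = 40) {
  repeat {
    n <- sample(4:n_max, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# Random square rater table over k categories.
rand_square_tab <- function(k = 4, n_max = 60) {
  n <- sample(k:n_max, 1)
  matrix(as.vector(stats::rmultinom(1, n, prob = stats::runif(k * k, 0.05, 1))),
         k, k)
}

# Random pair of score distributions over 0..6.
rand_dists <- function(n_max = 30) {
  mk <- function(group) {
    n <- sample(2:n_max, 1)
    score_distribution(sample(0:6, n, replace = TRUE,
                              prob = stats::runif(7, 0.05, 1)), group)
  }
  list(pos = mk("FCD"), neg = mk("control"))
}

# Brute-force pairwise AUC: expand each distribution to per-ear scores
# and average the 0/0.5/1 pair kernel over every pos x neg pair.
auc_pairwise_oracle <- function(dist_pos, dist_neg) {
  sp <- rep(0:6, dist_pos$counts)
  sn <- rep(0:6, dist_neg$counts)
  grid <- outer(sp, sn, function(a, b) (a < b) + 0.5 * (a == b))
  mean(grid)
}

# Expand a two-observer cross-tab into paired rating vectors
# (rows = observer 2, columns = observer 1).
crosstab_to_pairs <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  obs2 <- rep(idx[, 1] - 1L, tab[idx])
  obs1 <- rep(idx[, 2] - 1L, tab[idx])
  list(obs1 = obs1, obs2 = obs2)
}
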