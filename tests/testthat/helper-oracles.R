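# Independent brute-force oracles used to validate the package's
# statistical primitives. These deliberately avoid the code paths (and
# library routines) used by the implementation.

# Classical rank-difference Spearman formula, valid for tie-free vectors:
# rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
oracle_spearman_tiefree <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Mann-Whitney U for group a (pairs with a_i > b_j, ties counted half)
oracle_u_stat <- function(a, b) {
  sum(vapply(a, function(ai) sum(ai > b) + 0.5 * sum(ai == b), numeric(1)))
}

# Exact two-sided p by full enumeration of all C(n_a + n_b, n_a) group
# labelings of the pooled data
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_obs <- oracle_u_stat(a, b)
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) {
    oracle_u_stat(pooled[idx], pooled[-idx])
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Naive O(n^3) complete-linkage agglomeration; returns merge heights in
# merge order
oracle_complete_linkage_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Small labelled expression matrix for hand-checked fixtures
make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(genes)) sprintf("g%d", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) sprintf("s%d", seq_len(ncol(m))) else samples
  m
}

# Random positive expression matrix with unique values (tie-free ranks)
random_expr <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_expr(matrix(stats::rlnorm(n_genes * n_samples), n_genes, n_samples))
}
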