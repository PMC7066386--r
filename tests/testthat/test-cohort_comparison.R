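test_that("median split sends at-median samples to the low group", {
  e <- make_expr(rbind(GZMA = c(1, 2, 3, 4)), genes = "GZMA")
  sp <- median_split(e, "GZMA")
  expect_setequal(sp$group_a_ids, c("s3", "s4"))
  expect_setequal(sp$group_b_ids, c("s1", "s2"))

  e2 <- make_expr(rbind(GZMA = c(1, 2, 2, 5)), genes = "GZMA")
  sp2 <- median_split(e2, "GZMA")
  expect_equal(sp2$group_a_ids, "s4")        # only the value above median 2
  expect_length(sp2$group_b_ids, 3L)

  # 214 distinct values: the even 107/107 split of the REMBRANDT-sized cohort
  set.seed(71)
  e3 <- make_expr(rbind(GZMA = sample(seq_len(1000), 214)), genes = "GZMA")
  sp3 <- median_split(e3, "GZMA")
  expect_equal(lengths(sp3[c("group_a_ids", "group_b_ids")]),
               c(group_a_ids = 107L, group_b_ids = 107L))

  const <- make_expr(rbind(GZMA = rep(2, 6)), genes = "GZMA")
  expect_error(median_split(const, "GZMA"), "degenerate")
  expect_error(median_split(e, "ABSENT"), "not in matrix")
})

test_that("mann_whitney exact p matches hand examples and symmetry", {
  mw <- mann_whitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 2 / 6, tolerance = 1e-12)

  # identical groups: U at its null mean, two-sided p exactly 1
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3), mode = "normal_approx")
  expect_equal(mw2$u_statistic, 4.5)
  expect_equal(mw2$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney(c(1, 1, 2), c(3, 4, 5), mode = "exact"), "tie-free")
  expect_error(mann_whitney(rnorm(20), rnorm(20), mode = "exact"), "<= 25")
})

test_that("exact p equals full labeling enumeration for all n_a, n_b <= 6", {
  set.seed(81)
  for (na in 2:6) {
    for (nb in 2:6) {
      x <- sample(seq_len(1000), na + nb)  # tie-free
      a <- x[seq_len(na)]; b <- x[-seq_len(na)]
      mw <- mann_whitney(a, b, mode = "exact")
      expect_equal(mw$u_statistic, oracle_u_stat(a, b))
      expect_equal(mw$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12,
                   label = sprintf("exact p (n_a=%d, n_b=%d)", na, nb))
    }
  }
})

test_that("normal approximation tracks the exact law and U identities hold", {
  set.seed(91)
  for (i in 1:10) {
    x <- sample(seq_len(10000), 16)  # tie-free across the pooled sample
    a <- x[1:8]; b <- x[9:16]
    ex <- mann_whitney(a, b, mode = "exact")
    ap <- mann_whitney(a, b, mode = "normal_approx")
    expect_lt(abs(ex$p_value - ap$p_value), 0.02)

    # U_a + U_b = n_a * n_b; label swap preserves the two-sided p
    sw <- mann_whitney(b, a, mode = "exact")
    expect_equal(ex$u_statistic + sw$u_statistic, 64)
    expect_equal(ex$p_value, sw$p_value, tolerance = 1e-12)

    # invariance under a common strictly increasing transform
    tr <- mann_whitney(log1p(a), log1p(b), mode = "exact")
    expect_equal(tr$u_statistic, ex$u_statistic)
    expect_equal(tr$p_value, ex$p_value, tolerance = 1e-12)
  }
})

test_that("compare_features reports per-gene tests with direction and BH option", {
  set.seed(101)
  n <- 30
  genes <- sprintf("gene%02d", 1:20)
  expr <- make_expr(matrix(rlnorm(20 * 2 * n), 20, 2 * n), genes = genes)
  split <- structure(list(group_a_ids = colnames(expr)[1:n],
                          group_b_ids = colnames(expr)[(n + 1):(2 * n)],
                          rule = "synthetic"), class = "group_split")
  res <- compare_features(expr, split, c(genes[1:5], "ABSENT"))
  expect_equal(nrow(res), 5L)
  expect_equal(attr(res, "missing_features"), "ABSENT")
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  ok <- res$median_a != res$median_b
  expect_equal(res$direction[ok],
               ifelse(res$median_a[ok] > res$median_b[ok], "a_higher", "b_higher"))
  expect_true(all(is.na(res$adjusted_p)))
  res_bh <- compare_features(expr, split, genes, adjust = "benjamini_hochberg")
  expect_true(all(res_bh$adjusted_p >= res_bh$p_value - 1e-12))

  # two features with identical data give identical p-values
  dup <- rbind(expr, gene_copy = expr["gene01", ])
  rd <- compare_features(dup, split, c("gene01", "gene_copy"))
  expect_equal(rd$p_value[1], rd$p_value[2])
})

test_that("a location-shifted gene attains the smallest p in most replicates", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(200 + seed)
    n <- 30
    genes <- sprintf("gene%02d", 1:20)
    vals <- matrix(rnorm(20 * 2 * n), 20, 2 * n)
    vals[1, 1:n] <- vals[1, 1:n] + 2  # 2 SD shift in group A
    expr <- make_expr(vals, genes = genes)
    split <- structure(list(group_a_ids = colnames(expr)[1:n],
                            group_b_ids = colnames(expr)[(n + 1):(2 * n)],
                            rule = "shifted"), class = "group_split")
    res <- compare_features(expr, split, genes)
    if (res$feature[which.min(res$p_value)] == "gene01") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("cluster splits validate their labels", {
  ass <- data.frame(sample_id = c("s1", "s2", "s3"),
                    assigned_cluster = c("CIC2", "CIC4", "CIC2"))
  sp <- cluster_split(ass, "CIC2", "CIC4")
  expect_setequal(sp$group_a_ids, c("s1", "s3"))
  expect_equal(sp$group_b_ids, "s2")
  expect_error(cluster_split(ass, "CIC2", "CIC9"), "unknown cluster")
})
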