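# Two-group cohort comparisons: split a cohort by cluster assignment or
# by median expression of a surrogate gene (e.g. GZMA as a proxy for
# immune infiltration), then compare per-gene expression between the
# groups with the Mann-Whitney (Wilcoxon rank-sum) test.

#' Median split of a cohort on one gene
#'
#' Samples with expression strictly greater than the cohort median form
#' the high group; samples at or below the median form the low group.
#' With an even number of distinct values this yields an even split (e.g.
#' 107/107 for a 214-sample cohort).
#'
#' @param expr genes x samples numeric matrix.
#' @param gene gene identifier present in `expr`.
#' @return a `group_split` object: list with `group_a_ids` (high),
#'   `group_b_ids` (low) and a human-readable `rule`.
#' @export
median_split <- function(expr, gene) {
  validate_expression_matrix(expr, "log")
  if (!gene %in% rownames(expr)) stop("gene not in matrix: ", gene)
  v <- expr[gene, ]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need >= 2 samples with non-missing values")
  if (length(unique(v)) == 1L)
    stop("all values of ", gene, " identical; median split degenerate")
  med <- stats::median(v)
  structure(list(group_a_ids = names(v)[v > med],
                 group_b_ids = names(v)[v <= med],
                 rule = sprintf("%s > median vs <= median", gene)),
            class = "group_split")
}

#' Group split from a cluster-assignment table
#'
#' @param assignments data.frame as returned by
#'   [classify_nearest_centroid()] (columns `sample_id`,
#'   `assigned_cluster`).
#' @param cluster_a,cluster_b cluster labels for the two groups.
#' @return a `group_split` object (group A first).
#' @export
cluster_split <- function(assignments, cluster_a, cluster_b) {
  stopifnot(is.data.frame(assignments),
            all(c("sample_id", "assigned_cluster") %in% names(assignments)))
  known <- unique(stats::na.omit(assignments$assigned_cluster))
  for (cl in c(cluster_a, cluster_b))
    if (!cl %in% known) stop("unknown cluster label: ", cl)
  a <- assignments$sample_id[!is.na(assignments$assigned_cluster) &
                               assignments$assigned_cluster == cluster_a]
  b <- assignments$sample_id[!is.na(assignments$assigned_cluster) &
                               assignments$assigned_cluster == cluster_b]
  structure(list(group_a_ids = a, group_b_ids = b,
                 rule = sprintf("%s vs %s", cluster_a, cluster_b)),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat("Group split [", x$rule, "]: ", length(x$group_a_ids), " vs ",
      length(x$group_b_ids), " samples\n", sep = "")
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Returns the U statistic for the first group (number of pairs `(i, j)`
#' with `a_i > b_j`, counting ties as half) and a two-sided p-value. Mode
#' `exact` enumerates the permutation null (no ties, `n_a + n_b <= 25`
#' required); `normal_approx` uses the tie-corrected normal approximation
#' with continuity correction; `auto` (default) picks exact whenever its
#' preconditions hold.
#'
#' @param a,b numeric vectors (non-missing values are used).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `u_statistic`, `p_value` and `mode_used`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  n <- length(a) + length(b)
  if (mode == "exact") {
    if (ties) stop("exact mode requires tie-free data")
    if (n > 25L) stop("exact mode requires n_a + n_b <= 25")
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = !ties && n <= 25L)
  w <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(u_statistic = unname(w$statistic),
       p_value = w$p.value,
       mode_used = if (use_exact) "exact" else "normal_approx")
}

#' Compare features between two sample groups
#'
#' Runs [mann_whitney()] per feature on the two groups of a split and
#' reports the statistic, p-value, group medians and direction. Features
#' absent from the matrix are reported in the `missing_features` attribute
#' (and a message), not treated as fatal.
#'
#' @param expr genes x samples numeric matrix.
#' @param split a `group_split` ([median_split()] / [cluster_split()]).
#' @param features character vector of gene identifiers to test.
#' @param adjust `"none"` (default, per-gene p-values as printed) or
#'   `"benjamini_hochberg"` for FDR adjustment across the feature list.
#' @param mode test mode passed to [mann_whitney()].
#' @return data.frame with one row per found feature: `feature`,
#'   `u_statistic`, `p_value`, `median_a`, `median_b`, `direction`
#'   (a_higher/b_higher/equal) and `adjusted_p` (NA when `adjust="none"`).
#' @export
compare_features <- function(expr, split, features,
                             adjust = c("none", "benjamini_hochberg"),
                             mode = "auto") {
  adjust <- match.arg(adjust)
  validate_expression_matrix(expr, "log")
  stopifnot(inherits(split, "group_split"))
  ga <- intersect(split$group_a_ids, colnames(expr))
  gb <- intersect(split$group_b_ids, colnames(expr))
  if (length(ga) == 0L || length(gb) == 0L)
    stop("both groups must contain samples present in the matrix")
  if (length(intersect(ga, gb)) > 0L) stop("groups overlap")
  features <- unique(features)
  found <- features[features %in% rownames(expr)]
  missing <- setdiff(features, found)
  if (length(missing) > 0L)
    message("feature(s) not in matrix, skipped: ", paste(missing, collapse = ", "))
  rows <- lapply(found, function(g) {
    mw <- mann_whitney(expr[g, ga], expr[g, gb], mode = mode)
    ma <- stats::median(expr[g, ga], na.rm = TRUE)
    mb <- stats::median(expr[g, gb], na.rm = TRUE)
    data.frame(feature = g, u_statistic = mw$u_statistic,
               p_value = mw$p_value, median_a = ma, median_b = mb,
               direction = if (ma > mb) "a_higher" else if (mb > ma) "b_higher" else "equal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (adjust == "benjamini_hochberg")
    stats::p.adjust(out$p_value, method = "BH") else NA_real_
  attr(out, "missing_features") <- missing
  out
}
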