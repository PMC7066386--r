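# Per-sample immune cell-type scores over a signature compendium.
# Scores feed the sample-by-cell-type heatmap and, indirectly, the CIC
# interpretation; the classifier itself works on genes, not scores.

#' Z-score each gene across samples
#'
#' Standardises every gene row to mean 0 and population standard deviation
#' 1 across the cohort (divisor n, not n-1, so a two-sample row `[2, 4]`
#' maps to `[-1, 1]`). Constant genes have no scale and map to all-zero
#' rows with a warning. Missing values are ignored in the moments and stay
#' missing in the output.
#'
#' @param expr genes x samples numeric matrix with >= 2 samples.
#' @return matrix of the same shape, per-gene standardised.
#' @export
zscore_genes <- function(expr) {
  validate_expression_matrix(expr, "log")
  if (ncol(expr) < 2L)
    stop("z-scores are undefined for a single-sample matrix")
  mu <- rowMeans(expr, na.rm = TRUE)
  centred <- expr - mu
  sd_pop <- sqrt(rowMeans(centred^2, na.rm = TRUE))
  const <- sd_pop == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) mapped to all-zero z-scores")
    sd_pop[const] <- 1
  }
  # constant rows: centred is 0 (or NA) and sd was reset to 1, so they are
  # already all-zero with missingness preserved
  centred / sd_pop
}

#' Score samples for each immune cell type of a compendium
#'
#' For every cell type in the compendium, computes one unitless score per
#' sample summarising the expression of that type's signature genes.
#'
#' Two methods are provided. `mean_z` (default): the mean, over the
#' signature genes present in the data, of cohort z-scored expression
#' ([zscore_genes()]). `rank_enrichment`: the mean within-sample rank of
#' the signature genes, with ranks over all genes rescaled to `[0, 1]`
#' (mid-ranks for ties; 0 = lowest-expressed gene in the sample, 1 =
#' highest). `mean_z` compares samples within the cohort;
#' `rank_enrichment` is cohort-free and invariant to monotone per-sample
#' transforms.
#'
#' Cell types whose signature coverage (fraction of signature genes found
#' in the matrix) falls below `min_coverage` get missing scores, never
#' silent zeros.
#'
#' @param expr genes x samples numeric matrix.
#' @param compendium a [signature_compendium()].
#' @param method `"mean_z"` or `"rank_enrichment"`.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present to emit a score (default 0.5).
#' @return an `immune_scores` object: list with `scores` (cell types x
#'   samples matrix), `coverage` (named fraction per cell type), `method`
#'   and `min_coverage`.
#' @export
score_samples <- function(expr, compendium,
                          method = c("mean_z", "rank_enrichment"),
                          min_coverage = 0.5) {
  method <- match.arg(method)
  validate_expression_matrix(expr, "log")
  if (!inherits(compendium, "signature_compendium"))
    compendium <- signature_compendium(compendium)
  universe <- compendium_universe(compendium)
  if (length(intersect(universe, rownames(expr))) == 0L)
    stop("no overlap between the compendium gene universe and the expression matrix")

  basis <- switch(method,
    mean_z = zscore_genes(expr),
    rank_enrichment = {
      n <- nrow(expr)
      r <- apply(expr, 2L, rank, ties.method = "average", na.last = "keep")
      if (n > 1L) (r - 1) / (n - 1) else r * 0
    })

  coverage <- vapply(compendium, function(g) {
    mean(g %in% rownames(expr))
  }, numeric(1L))
  scores <- t(vapply(seq_along(compendium), function(i) {
    genes <- intersect(compendium[[i]], rownames(expr))
    if (coverage[[i]] < min_coverage || length(genes) == 0L)
      return(rep(NA_real_, ncol(expr)))
    colMeans(basis[genes, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(expr))))
  dimnames(scores) <- list(names(compendium), colnames(expr))
  structure(list(scores = scores, coverage = coverage,
                 method = method, min_coverage = min_coverage),
            class = "immune_scores")
}

#' @export
print.immune_scores <- function(x, ...) {
  cat("Immune scores (", x$method, "): ", nrow(x$scores), " cell types x ",
      ncol(x$scores), " samples; ", sum(x$coverage < x$min_coverage),
      " type(s) below coverage ", x$min_coverage, "\n", sep = "")
  invisible(x)
}

#' Write an immune score matrix (and its coverage) as TSV
#'
#' @param scores an `immune_scores` object.
#' @param path output path for the score table; the coverage table is
#'   written next to it with suffix `.coverage.tsv`.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "immune_scores"))
  df <- data.frame(cell_type = rownames(scores$scores), scores$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- data.frame(cell_type = names(scores$coverage),
                    coverage = unname(scores$coverage))
  utils::write.table(cov, paste0(sub("\\.tsv$", "", path), ".coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
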