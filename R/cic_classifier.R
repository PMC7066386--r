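# Nearest-centroid assignment of tumours to consensus immune clusters
# (CICs). The centroid of a cluster is the per-gene mean expression over
# its member samples; a tumour is assigned to the cluster whose centroid
# it correlates with best by Spearman rank correlation, making the
# classifier invariant to any strictly increasing per-sample transform.

#' Compute cluster centroids from a labelled reference cohort
#'
#' The centroid of a cluster is the arithmetic mean, gene by gene, of the
#' expression of the samples labelled with that cluster.
#'
#' @param expr genes x samples numeric matrix.
#' @param labels cluster label per sample: either a vector named by sample
#'   id, or an unnamed vector aligned with `colnames(expr)`. Factor level
#'   order (or first-appearance order) fixes the centroid column order.
#' @param gene_subset optional character vector restricting the centroid to
#'   a gene universe (e.g. the 380-gene immune compendium); default all
#'   genes in `expr`.
#' @return genes x clusters numeric matrix (see [validate_centroid_set()]).
#' @export
compute_centroids <- function(expr, labels, gene_subset = NULL) {
  validate_expression_matrix(expr, "log")
  if (!is.null(names(labels))) {
    missing_samples <- setdiff(colnames(expr), names(labels))
    if (length(missing_samples) > 0L)
      stop("no label for sample(s): ", paste(utils::head(missing_samples, 5L), collapse = ", "))
    labels <- labels[colnames(expr)]
  } else if (length(labels) != ncol(expr)) {
    stop("labels must be named by sample id or aligned with the samples")
  }
  lv <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  labels <- as.character(labels)
  empty <- setdiff(lv, labels)
  if (length(empty) > 0L)
    stop("cluster(s) with zero samples: ", paste(empty, collapse = ", "))
  genes <- if (is.null(gene_subset)) rownames(expr) else intersect(gene_subset, rownames(expr))
  if (length(genes) == 0L)
    stop("gene_subset has no overlap with the expression matrix")
  cent <- vapply(lv, function(cl) {
    rowMeans(expr[genes, labels == cl, drop = FALSE], na.rm = TRUE)
  }, numeric(length(genes)))
  cent[is.nan(cent)] <- NA_real_
  rownames(cent) <- genes
  validate_centroid_set(cent)
  cent
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (average ranks under ties), i.e. the
#' tie-corrected Spearman coefficient. Pairs with a missing value in
#' either vector are removed first; at least 3 complete pairs are
#' required, and a vector that is constant after removal has undefined
#' rank correlation and raises an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Classify samples to their nearest centroid by Spearman correlation
#'
#' For each sample, the Spearman correlation with every centroid is
#' computed over the genes shared between the sample (non-missing) and the
#' centroid table, and the sample is assigned to the cluster with the
#' highest coefficient. Exact ties assign the first cluster in centroid
#' column order and set `tie_flag`. Samples whose usable gene overlap
#' falls below `min_overlap_fraction` of the centroid genes (or below 3
#' genes), or whose expression is constant over the shared genes, are
#' marked unclassifiable with a reason rather than dropped.
#'
#' @param expr genes x samples numeric matrix.
#' @param centroids genes x clusters numeric matrix
#'   (see [read_centroids()] / [compute_centroids()]).
#' @param min_overlap_fraction minimum usable fraction of the centroid gene
#'   list per sample (default 0.5, guarding against platform gene loss).
#' @return data.frame with one row per sample: `sample_id`,
#'   `assigned_cluster` (NA if unclassifiable), `tie_flag`, `n_genes_used`,
#'   `reason` (NA when classified) and one `rho_<cluster>` column per
#'   centroid.
#' @export
classify_nearest_centroid <- function(expr, centroids, min_overlap_fraction = 0.5) {
  validate_expression_matrix(expr, "log")
  validate_centroid_set(centroids)
  if (min_overlap_fraction < 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in [0, 1]")
  clusters <- colnames(centroids)
  shared0 <- intersect(rownames(expr), rownames(centroids))
  min_genes <- max(3L, ceiling(min_overlap_fraction * nrow(centroids)))

  res <- lapply(colnames(expr), function(s) {
    rho <- rep(NA_real_, length(clusters))
    names(rho) <- clusters
    out <- list(sample_id = s, assigned_cluster = NA_character_,
                tie_flag = FALSE, n_genes_used = 0L, reason = NA_character_,
                rho = rho)
    v <- expr[shared0, s]
    usable <- shared0[is.finite(v)]
    out$n_genes_used <- length(usable)
    if (length(usable) < min_genes) {
      out$reason <- sprintf("insufficient gene overlap (%d < %d)",
                            length(usable), min_genes)
      return(out)
    }
    sv <- expr[usable, s]
    if (length(unique(sv)) == 1L) {
      out$reason <- "constant expression over centroid genes"
      return(out)
    }
    for (cl in clusters) {
      cv <- centroids[usable, cl]
      ok <- is.finite(cv)
      if (sum(ok) >= 3L && length(unique(cv[ok])) > 1L &&
          length(unique(sv[ok])) > 1L)
        out$rho[[cl]] <- spearman_rho(sv[ok], cv[ok])
    }
    if (all(is.na(out$rho))) {
      out$reason <- "no centroid with a defined correlation"
      return(out)
    }
    best <- max(out$rho, na.rm = TRUE)
    hits <- which(!is.na(out$rho) & out$rho == best)
    out$assigned_cluster <- clusters[hits[1L]]
    out$tie_flag <- length(hits) > 1L
    out
  })

  rho_mat <- do.call(rbind, lapply(res, `[[`, "rho"))
  colnames(rho_mat) <- paste0("rho_", clusters)
  out <- data.frame(
    sample_id = vapply(res, `[[`, character(1L), "sample_id"),
    assigned_cluster = vapply(res, `[[`, character(1L), "assigned_cluster"),
    tie_flag = vapply(res, `[[`, logical(1L), "tie_flag"),
    n_genes_used = vapply(res, `[[`, integer(1L), "n_genes_used"),
    reason = vapply(res, `[[`, character(1L), "reason"),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(rho_mat))
}
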