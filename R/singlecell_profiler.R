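# Marker-rule classification of single cells into tumour and immune
# compartments, per-cell immunosuppressive-gene burden, receptor-ligand
# co-expression percentages, and hierarchical clustering for heatmap
# display. Positivity follows the "> 0 scored positive" convention:
# expression strictly above the threshold counts, exact zeros do not.

#' Marker rule set for compartment classification
#'
#' A cell is *immune* if any immune marker is positive, *tumour* if all
#' tumour markers are positive and no immune marker is, *ambiguous* if
#' both rule sets fire, and *other* otherwise.
#'
#' @param tumour_markers genes that must all be positive (default
#'   `c("SOX9", "EGFR")`).
#' @param immune_markers genes of which any one positive suffices (default
#'   `"PTPRC"`, i.e. CD45).
#' @param positivity_threshold exclusive lower bound for positivity
#'   (default 0: any expression above zero is positive).
#' @return a `marker_rules` object.
#' @export
marker_rules <- function(tumour_markers = c("SOX9", "EGFR"),
                         immune_markers = "PTPRC",
                         positivity_threshold = 0) {
  tumour_markers <- unique(as.character(tumour_markers))
  immune_markers <- unique(as.character(immune_markers))
  if (length(tumour_markers) == 0L || length(immune_markers) == 0L)
    stop("both marker sets must be non-empty")
  if (length(intersect(tumour_markers, immune_markers)) > 0L)
    stop("tumour and immune marker sets must be disjoint")
  if (positivity_threshold < 0) stop("positivity threshold must be >= 0")
  structure(list(tumour_markers = tumour_markers,
                 immune_markers = immune_markers,
                 positivity_threshold = positivity_threshold),
            class = "marker_rules")
}

#' Shipped marker-rule presets
#'
#' Two tumour-marker conventions are in circulation for GBM single-cell
#' data: SOX9+EGFR and SOX2+EGFR joint positivity (both with PTPRC
#' defining immune cells). Both are shipped as presets rather than
#' resolving the discrepancy.
#'
#' @param name `"sox9_egfr"` (default) or `"sox2_egfr"`.
#' @return a `marker_rules` object.
#' @export
marker_rules_preset <- function(name = c("sox9_egfr", "sox2_egfr")) {
  name <- match.arg(name)
  switch(name,
    sox9_egfr = marker_rules(c("SOX9", "EGFR"), "PTPRC", 0),
    sox2_egfr = marker_rules(c("SOX2", "EGFR"), "PTPRC", 0))
}

#' Classify single cells into compartments by marker rules
#'
#' @param expr genes x cells numeric matrix. All marker genes must be
#'   present (error naming the first missing one otherwise).
#' @param rules a [marker_rules()] object.
#' @return data.frame with `cell_id` and `compartment` (factor with levels
#'   tumour, immune, ambiguous, other).
#' @export
classify_cells <- function(expr, rules = marker_rules_preset()) {
  validate_expression_matrix(expr, "log")
  stopifnot(inherits(rules, "marker_rules"))
  needed <- c(rules$tumour_markers, rules$immune_markers)
  absent <- setdiff(needed, rownames(expr))
  if (length(absent) > 0L)
    stop("marker gene(s) missing from the matrix: ", paste(absent, collapse = ", "))
  thr <- rules$positivity_threshold
  pos <- function(g) expr[g, , drop = FALSE] > thr
  tumour_fire <- colSums(pos(rules$tumour_markers), na.rm = TRUE) ==
    length(rules$tumour_markers)
  immune_fire <- colSums(pos(rules$immune_markers), na.rm = TRUE) > 0L
  compartment <- rep("other", ncol(expr))
  compartment[tumour_fire] <- "tumour"
  compartment[immune_fire] <- "immune"
  compartment[tumour_fire & immune_fire] <- "ambiguous"
  data.frame(cell_id = colnames(expr),
             compartment = factor(compartment,
                                  levels = c("tumour", "immune", "ambiguous", "other")),
             stringsAsFactors = FALSE)
}

#' Per-cell immunosuppressive-gene burden
#'
#' Counts, for each cell, how many distinct genes of an immunomodulatory
#' panel are expressed above the threshold. Panel genes absent from the
#' matrix are counted as not expressed, with a warning.
#'
#' @param expr genes x cells numeric matrix.
#' @param panel character vector of panel genes.
#' @param threshold exclusive positivity bound (default 0).
#' @return named integer vector, one count per cell.
#' @export
burden_count <- function(expr, panel, threshold = 0) {
  validate_expression_matrix(expr, "log")
  panel <- unique(as.character(panel))
  present <- intersect(panel, rownames(expr))
  absent <- setdiff(panel, rownames(expr))
  if (length(present) == 0L)
    stop("no panel gene found in the expression matrix")
  if (length(absent) > 0L)
    warning(length(absent), " panel gene(s) absent from the matrix, counted as not expressed: ",
            paste(utils::head(absent, 5L), collapse = ", "))
  counts <- colSums(expr[present, , drop = FALSE] > threshold, na.rm = TRUE)
  storage.mode(counts) <- "integer"
  counts
}

#' Co-expression percentages for a gene pair within a cell subset
#'
#' Reports which percentage of the subset expresses either gene and both
#' genes above the threshold (e.g. a receptor-ligand pair such as
#' HAVCR2/LGALS9 within the immune compartment).
#'
#' @param expr genes x cells numeric matrix.
#' @param gene_a,gene_b gene identifiers, both present in `expr`.
#' @param subset cell ids to restrict to (default: all cells).
#' @param threshold exclusive positivity bound (default 0).
#' @return named numeric vector `c(pct_either = , pct_both = )`, percentages
#'   in `[0, 100]`.
#' @export
coexpression_fraction <- function(expr, gene_a, gene_b, subset = NULL,
                                  threshold = 0) {
  validate_expression_matrix(expr, "log")
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(expr)) stop("gene not in matrix: ", g)
  if (is.null(subset)) subset <- colnames(expr)
  subset <- intersect(subset, colnames(expr))
  if (length(subset) == 0L) stop("empty cell subset")
  a <- expr[gene_a, subset] > threshold
  b <- expr[gene_b, subset] > threshold
  a[is.na(a)] <- FALSE
  b[is.na(b)] <- FALSE
  c(pct_either = 100 * mean(a | b), pct_both = 100 * mean(a & b))
}

#' Agglomerative clustering on untransformed values
#'
#' Complete-linkage hierarchical clustering on Euclidean distances of the
#' untransformed expression values, for ordering heatmap rows/columns.
#' Missing values are treated as zero with a warning. A single item yields
#' a trivial one-leaf result.
#'
#' @param expr genes x cells (or genes x samples) numeric matrix.
#' @param axis `"cells"` (cluster columns) or `"genes"` (cluster rows).
#' @return list with `order` (integer leaf order), `labels`, and `hclust`
#'   (the [stats::hclust] object carrying merge heights and topology;
#'   NULL for a single item).
#' @export
hierarchical_cluster <- function(expr, axis = c("cells", "genes")) {
  axis <- match.arg(axis)
  validate_expression_matrix(expr, "log")
  m <- if (axis == "cells") t(expr) else expr
  if (anyNA(m)) {
    warning("missing values treated as 0 for clustering")
    m[is.na(m)] <- 0
  }
  if (nrow(m) < 2L)
    return(list(order = seq_len(nrow(m)), labels = rownames(m), hclust = NULL))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  list(order = hc$order, labels = rownames(m), hclust = hc)
}
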