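# Synthetic bulk cohorts and single-cell mixtures with known ground
# truth. Bulk samples are noisy log-normal mixtures of cell-type
# signature profiles with cluster-specific infiltration levels (the
# structure the CIC classifier assumes); single cells are drawn from
# tumour / immune / neuronal populations with population-specific marker
# and immunomodulatory-gene expression probabilities and optional
# dropout. All randomness flows from the single seed in the config.

# ---- compendium and infiltration defaults ------------------------------

.default_cell_types <- c(
  "T_CD8", "T_CD4_memory", "T_helper1", "T_helper2", "T_helper17",
  "T_regulatory", "T_gamma_delta", "T_central_memory", "T_effector_memory",
  "NK_cells", "NK_CD56bright", "NK_CD56dim", "NKT_cells", "B_cells",
  "Plasma_cells", "Dendritic_cells", "Dendritic_activated",
  "Dendritic_plasmacytoid", "Macrophages", "Monocytes", "Neutrophils",
  "Eosinophils", "Mast_cells", "Cytotoxic_cells")

#' Synthetic immune signature compendium
#'
#' A compendium with the footprint of the published immunome compendium:
#' 24 immune cell types covering 380 marker genes in total (disjoint
#' synthetic gene identifiers `IMM_Gxxx`).
#'
#' @param n_types number of cell types (default 24).
#' @param n_genes_total total number of signature genes (default 380),
#'   partitioned as evenly as possible across types.
#' @return a [signature_compendium()].
#' @export
synthetic_compendium <- function(n_types = 24, n_genes_total = 380) {
  stopifnot(n_types >= 1, n_genes_total >= n_types)
  sizes <- rep(n_genes_total %/% n_types, n_types)
  extra <- n_genes_total %% n_types
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  genes <- sprintf("IMM_G%03d", seq_len(n_genes_total))
  idx <- split(genes, rep(seq_len(n_types), sizes))
  nms <- if (n_types == length(.default_cell_types)) .default_cell_types
         else sprintf("cell_type_%02d", seq_len(n_types))
  signature_compendium(stats::setNames(idx, nms))
}

#' Cluster infiltration profiles for bulk simulation
#'
#' Returns per-cluster mean infiltration levels (log-scale additive
#' effects) over the cell types of a compendium. The shipped two-cluster
#' preset contrasts an immune-hot cluster (strong lymphoid and cytotoxic
#' infiltration) with an immune-cold cluster (weak infiltration, mild
#' myeloid bias), mirroring the high- vs low-infiltrate contrast between
#' immune clusters of bulk GBM cohorts. The profiles differ in shape, not
#' just overall level, so rank-based classification has signal.
#'
#' @param cell_types character vector of cell-type names.
#' @param n_clusters 2 (default, hot-vs-cold) or 6 (a graded CIC-like
#'   panel obtained by interpolating between the two extremes with
#'   alternating lymphoid/myeloid emphasis).
#' @return named list of named numeric vectors (one per cluster).
#' @export
infiltration_profiles <- function(cell_types, n_clusters = 2) {
  k <- length(cell_types)
  lymphoid <- grepl("^(T_|NK|B_|Plasma|Cytotoxic)", cell_types)
  base_hot <- ifelse(lymphoid, 2.0, 1.0)
  base_cold <- ifelse(lymphoid, 0.2, 0.6)
  names(base_hot) <- names(base_cold) <- cell_types
  if (n_clusters == 2) {
    return(list(immune_hot = base_hot, immune_cold = base_cold))
  }
  mix <- seq(1, 0, length.out = n_clusters)
  out <- lapply(seq_len(n_clusters), function(i) {
    w <- mix[[i]]
    prof <- w * base_hot + (1 - w) * base_cold
    # alternate emphasis so consecutive clusters differ in shape
    if (i %% 2 == 0) prof[!lymphoid] <- prof[!lymphoid] + 0.5
    prof
  })
  names(out) <- sprintf("CIC%d", seq_len(n_clusters))
  out
}

#' Configuration for a synthetic bulk cohort
#'
#' @param n_samples total number of samples (>= number of clusters).
#' @param clusters named list: per cluster, a named numeric vector of mean
#'   infiltration levels (log-scale) per cell type. All levels must be
#'   >= 0. Default: the two-cluster hot/cold preset over the compendium's
#'   cell types.
#' @param compendium a [signature_compendium()] (default
#'   [synthetic_compendium()]: 24 types, 380 genes).
#' @param noise_sd log-scale Gaussian noise SD per gene and sample
#'   (default 0.2).
#' @param n_background_genes cluster-independent genes added to the matrix
#'   (default 100).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_samples = 40, clusters = NULL,
                            compendium = synthetic_compendium(),
                            noise_sd = 0.2, n_background_genes = 100,
                            seed = 1) {
  if (!inherits(compendium, "signature_compendium"))
    compendium <- signature_compendium(compendium)
  if (is.null(clusters))
    clusters <- infiltration_profiles(names(compendium), 2)
  if (is.null(names(clusters)) || anyDuplicated(names(clusters)))
    stop("clusters must be a uniquely named list")
  for (cl in names(clusters)) {
    prof <- clusters[[cl]]
    if (is.null(names(prof)) || !all(names(compendium) %in% names(prof)))
      stop("cluster '", cl, "' must give a level for every compendium cell type")
    if (any(prof < 0)) stop("negative infiltration level in cluster '", cl, "'")
  }
  if (n_samples < length(clusters))
    stop("n_samples must be >= number of clusters")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples), clusters = clusters,
                 compendium = compendium, noise_sd = noise_sd,
                 n_background_genes = as.integer(n_background_genes),
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate a bulk tumour cohort with known cluster structure
#'
#' Each signature gene's expression is
#' `exp(baseline_g + level_c(type(g)) + N(0, noise_sd))`, where
#' `baseline_g` is a gene-specific log-baseline (N(2, 0.5), fixed by the
#' seed) and `level_c` the infiltration level of the sample's cluster for
#' the gene's cell type (genes in several signatures use the mean of
#' their types' levels). Background genes omit the cluster term. Samples
#' are assigned to clusters in round-robin order, so cluster sizes are
#' balanced.
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with `expr` (genes x samples matrix), `labels` (named
#'   character vector, true cluster per sample) and `infiltration`
#'   (data.frame of the true cluster x cell-type levels).
#' @export
simulate_bulk_cohort <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  set.seed(cfg$seed)
  comp <- cfg$compendium
  sig_genes <- compendium_universe(comp)
  bg_genes <- if (cfg$n_background_genes > 0)
    sprintf("BG_G%04d", seq_len(cfg$n_background_genes)) else character(0)
  genes <- c(sig_genes, bg_genes)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  cluster_names <- names(cfg$clusters)
  labels <- stats::setNames(
    rep(cluster_names, length.out = cfg$n_samples), samples)

  # mean infiltration level per signature gene within each cluster
  types_of_gene <- lapply(sig_genes, function(g)
    names(comp)[vapply(comp, function(s) g %in% s, logical(1L))])
  effect <- vapply(cluster_names, function(cl) {
    prof <- cfg$clusters[[cl]]
    vapply(types_of_gene, function(tt) mean(prof[tt]), numeric(1L))
  }, numeric(length(sig_genes)))
  rownames(effect) <- sig_genes

  baseline <- stats::rnorm(length(genes), mean = 2, sd = 0.5)
  names(baseline) <- genes
  logm <- matrix(baseline, nrow = length(genes), ncol = cfg$n_samples,
                 dimnames = list(genes, samples))
  logm[sig_genes, ] <- logm[sig_genes, ] + effect[, labels]
  if (cfg$noise_sd > 0)
    logm <- logm + matrix(stats::rnorm(length(logm), sd = cfg$noise_sd),
                          nrow = nrow(logm))
  expr <- exp(logm)
  infil <- do.call(rbind, lapply(cluster_names, function(cl)
    data.frame(cluster = cl, cell_type = names(comp),
               level = unname(cfg$clusters[[cl]][names(comp)]),
               stringsAsFactors = FALSE)))
  list(expr = expr, labels = labels, infiltration = infil)
}

# ---- single-cell simulation --------------------------------------------

#' Immunomodulatory panel used by the default single-cell simulation
#'
#' Checkpoint receptors/ligands, immunosuppressive cytokines and enzymes,
#' and HLA-G pathway members profiled per cell in GBM single-cell data.
#'
#' @return character vector of gene symbols.
#' @export
immunosuppressive_panel <- function() {
  c("HAVCR2", "LGALS9", "CD274", "PDCD1LG2", "CTLA4", "PDCD1", "BTLA",
    "VSIR", "FOXP3", "IL10", "IDO1", "TGFB1", "TGFB2", "TGFB3",
    "HLA-G", "LILRB1", "LILRB2", "NT5E", "ENTPD1")
}

.default_populations <- function() {
  panel_lo <- stats::setNames(rep(0.05, length(immunosuppressive_panel())),
                              immunosuppressive_panel())
  tumour_panel <- panel_lo
  tumour_panel[c("CD274", "PDCD1LG2", "NT5E", "TGFB2", "TGFB3", "HLA-G")] <-
    c(0.35, 0.25, 0.40, 0.45, 0.40, 0.30)
  immune_panel <- panel_lo
  immune_panel[c("CD274", "PDCD1LG2", "CTLA4", "PDCD1", "BTLA", "VSIR",
                 "FOXP3", "IL10", "IDO1", "TGFB1", "HLA-G", "LILRB1",
                 "LILRB2", "ENTPD1")] <-
    c(0.45, 0.35, 0.25, 0.25, 0.20, 0.40, 0.15, 0.40, 0.30, 0.70, 0.35,
      0.50, 0.45, 0.40)
  immune_panel[c("HAVCR2", "LGALS9")] <- 0  # drawn jointly via `pairs`
  other_panel <- panel_lo
  other_panel[c("TGFB2", "TGFB3")] <- c(0.30, 0.25)
  list(
    tumour = list(
      label = "tumour", proportion = 757 / 3589,
      markers = c(SOX9 = 1, SOX2 = 1, EGFR = 1, PTPRC = 0,
                  CD14 = 0, AIF1 = 0, MAP2 = 0.05, SNAP25 = 0.05),
      panel = tumour_panel, pairs = list()),
    immune = list(
      label = "immune", proportion = 1527 / 3589,
      markers = c(SOX9 = 0, SOX2 = 0, EGFR = 0, PTPRC = 1,
                  CD14 = 0.8, AIF1 = 0.85, MAP2 = 0, SNAP25 = 0),
      panel = immune_panel,
      pairs = list(list(genes = c("HAVCR2", "LGALS9"),
                        p_either = 0.92, p_both = 0.60))),
    other = list(
      label = "other", proportion = 1 - 757 / 3589 - 1527 / 3589,
      markers = c(SOX9 = 0.25, SOX2 = 0.3, EGFR = 0, PTPRC = 0,
                  CD14 = 0, AIF1 = 0, MAP2 = 0.9, SNAP25 = 0.85),
      panel = other_panel, pairs = list()))
}

#' Configuration for a synthetic single-cell mixture
#'
#' Each population is a list with `label`, `proportion`, `markers` (named
#' vector of expression probabilities for lineage marker genes), `panel`
#' (named vector of expression probabilities for immunomodulatory genes,
#' drawn independently) and optionally `pairs`: correlated gene pairs
#' given as `list(genes = c(a, b), p_either = , p_both = )`, drawn from
#' the 4-category joint distribution with the either-only mass split
#' evenly (independent Bernoulli genes cannot reach e.g. P(either)=0.92
#' with P(both)=0.60). Pair probabilities are final observed-expression
#' probabilities; dropout is not applied on top of them.
#'
#' The default emulates a GBM single-cell census of 3589 cells with
#' tumour (SOX9+/SOX2+/EGFR+), immune (PTPRC+, myeloid-marker-rich) and
#' neuronal populations in proportions 757:1527:1305, and the
#' HAVCR2/LGALS9 checkpoint pair co-expressed in immune cells at the
#' published 92%/60% rates.
#'
#' @param n_cells number of cells (default 3589).
#' @param populations list of population specs as above (default: the
#'   tumour/immune/other preset). Proportions must sum to 1.
#' @param dropout_rate probability that an expressed marker/panel gene is
#'   observed as zero (default 0: marker rules read the observed matrix).
#' @param n_background_genes housekeeping genes expressed in all
#'   populations (default 20), giving the clustering a common backbone.
#' @param poisson_counts if TRUE, magnitudes are rounded through a Poisson
#'   draw to integer counts (default FALSE: continuous magnitudes, since
#'   all downstream rules are threshold-based).
#' @param seed integer seed.
#' @return a `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_cells = 3589, populations = .default_populations(),
                          dropout_rate = 0, n_background_genes = 20,
                          poisson_counts = FALSE, seed = 1) {
  props <- vapply(populations, `[[`, numeric(1L), "proportion")
  if (abs(sum(props) - 1) > 1e-9) stop("population proportions must sum to 1")
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")
  for (p in populations) {
    probs <- c(p$markers, p$panel)
    if (any(probs < 0 | probs > 1)) stop("expression probabilities must be in [0, 1]")
    for (pr in p$pairs) {
      if (!is.character(pr$genes) || length(pr$genes) != 2L)
        stop("a pair must name exactly 2 genes")
      if (pr$p_both > pr$p_either || pr$p_either > 1 || pr$p_both < 0)
        stop("need 0 <= p_both <= p_either <= 1")
    }
  }
  labels <- vapply(populations, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("duplicate population labels")
  structure(list(n_cells = as.integer(n_cells), populations = populations,
                 dropout_rate = dropout_rate,
                 n_background_genes = as.integer(n_background_genes),
                 poisson_counts = isTRUE(poisson_counts),
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Simulate a single-cell mixture with known population labels
#'
#' Cells are assigned to populations by multinomial sampling of the
#' configured proportions. Each marker/panel gene is expressed in a cell
#' with probability `rate * (1 - dropout_rate)`; expressed genes get a
#' log-normal magnitude (meanlog 1, sdlog 0.5). Correlated pairs are
#' drawn from their joint distribution (see [sc_sim_config()]). All
#' values are non-negative; zeros are true negatives or dropouts.
#'
#' @param cfg a [sc_sim_config()].
#' @return list with `expr` (genes x cells matrix) and `labels` (named
#'   character vector, true population per cell).
#' @export
simulate_single_cells <- function(cfg = sc_sim_config()) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  pops <- cfg$populations
  pop_labels <- vapply(pops, `[[`, character(1L), "label")
  props <- vapply(pops, `[[`, numeric(1L), "proportion")
  cells <- sprintf("cell_%04d", seq_len(cfg$n_cells))
  labels <- stats::setNames(
    sample(pop_labels, cfg$n_cells, replace = TRUE, prob = props), cells)

  pair_genes <- unique(unlist(lapply(pops, function(p)
    lapply(p$pairs, `[[`, "genes"))))
  indep_genes <- unique(unlist(lapply(pops, function(p)
    c(names(p$markers), names(p$panel)))))
  bg_genes <- if (cfg$n_background_genes > 0)
    sprintf("HK_G%03d", seq_len(cfg$n_background_genes)) else character(0)
  genes <- c(setdiff(indep_genes, pair_genes), pair_genes, bg_genes)

  expr <- matrix(0, nrow = length(genes), ncol = cfg$n_cells,
                 dimnames = list(genes, cells))
  magnitude <- function(n) stats::rlnorm(n, meanlog = 1, sdlog = 0.5)

  for (p in pops) {
    idx <- which(labels == p$label)
    if (length(idx) == 0L) next
    own_pair_genes <- unlist(lapply(p$pairs, `[[`, "genes"))
    rates <- c(p$markers, p$panel)
    rates <- rates[setdiff(names(rates), own_pair_genes)]
    for (g in names(rates)) {
      on <- stats::rbinom(length(idx), 1L,
                          rates[[g]] * (1 - cfg$dropout_rate)) == 1L
      if (any(on)) expr[g, idx[on]] <- magnitude(sum(on))
    }
    for (pr in p$pairs) {
      p_both <- pr$p_both
      p_only <- (pr$p_either - pr$p_both) / 2
      cat4 <- sample(c("both", "a_only", "b_only", "neither"), length(idx),
                     replace = TRUE,
                     prob = c(p_both, p_only, p_only, 1 - pr$p_either))
      a_on <- cat4 %in% c("both", "a_only")
      b_on <- cat4 %in% c("both", "b_only")
      if (any(a_on)) expr[pr$genes[[1L]], idx[a_on]] <- magnitude(sum(a_on))
      if (any(b_on)) expr[pr$genes[[2L]], idx[b_on]] <- magnitude(sum(b_on))
    }
  }
  if (length(bg_genes) > 0) {
    on <- matrix(stats::rbinom(length(bg_genes) * cfg$n_cells, 1L, 0.85),
                 nrow = length(bg_genes)) == 1L
    mag <- matrix(magnitude(length(bg_genes) * cfg$n_cells),
                  nrow = length(bg_genes))
    expr[bg_genes, ] <- ifelse(on, mag, 0)
  }
  if (cfg$poisson_counts) {
    expr[] <- stats::rpois(length(expr), lambda = expr)
  }
  list(expr = expr, labels = labels)
}
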