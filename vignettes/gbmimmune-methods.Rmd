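---
title: "Methods: immune profiling of GBM transcriptomes with gbmimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune profiling of GBM transcriptomes with gbmimmune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmimmune)
```

# The problem

Glioblastoma (GBM) tumours differ widely in how much immune infiltrate
they carry and in how strongly that infiltrate is held in check by
inhibitory signalling. `gbmimmune` implements a compact computational
pipeline for characterising this spectrum from transcriptomes:

1. **Bulk immune scoring** — each tumour is scored against a compendium
   of immune cell-type marker signatures (the shipped synthetic
   compendium mirrors the footprint of published immunome compendia: 24
   cell types over 380 genes).
2. **Consensus immune cluster (CIC) assignment** — tumours are assigned
   to immune clusters by nearest-centroid classification: the centroid
   of a cluster is the per-gene mean expression over its member samples,
   and a tumour joins the cluster whose centroid it correlates with best
   by Spearman rank correlation.
3. **Single-cell compartment profiling** — cells are labelled tumour or
   immune by marker positivity rules, the number of distinct
   immunosuppressive genes each cell expresses is counted, and
   receptor–ligand co-expression percentages are reported.
4. **Two-group comparison** — per-gene Mann–Whitney tests between two
   cluster labels, or between high/low expressors of a surrogate gene
   split at the cohort median.

# Models and procedures

## Immune scoring

For a cohort matrix $X$ (genes $\times$ samples), the default score of
cell type $t$ in sample $j$ is

$$ s_{tj} = \frac{1}{|G_t|} \sum_{g \in G_t} z_{gj}, \qquad
   z_{gj} = \frac{x_{gj} - \bar x_g}{\sigma_g}, $$

where $G_t$ is the set of signature genes of $t$ found in the data and
$\sigma_g$ the *population* standard deviation of gene $g$ across
samples (divisor $n$; so a two-sample gene `[2, 4]` standardises to
`[-1, 1]`). The published description of the score is not explicit
about the formula, so the method is an explicit configuration field: a
`rank_enrichment` alternative scores the mean within-sample rank of the
signature genes, rescaled to $[0,1]$ with mid-ranks for ties. The
`mean_z` default positions each tumour relative to the cohort;
`rank_enrichment` is cohort-free and invariant to monotone per-sample
transforms. Whether input values are logged is the caller's declared
preprocessing; the score is computed on the scale supplied.

A cell type whose signature has less than `min_coverage` (default 50%)
of its genes present yields a missing score, never a silent zero; the
per-type coverage is always reported alongside. The 50% default guards
against platform gene loss (e.g. microarray vs RNAseq universes) while
still scoring types with partial coverage.

## Nearest-centroid classification

Spearman's coefficient is computed as the Pearson correlation of
mid-ranks, which is the tie-corrected form (the classical
$1 - 6\sum d_i^2 / (n(n^2-1))$ formula is biased under ties). Per
sample, correlation is computed over the genes shared between the
sample's non-missing values and the centroid table; a sample whose
usable overlap falls below `min_overlap_fraction` (default 0.5) of the
centroid genes, or below 3 genes, is marked unclassifiable with an
explicit reason. Exact rho ties assign the first cluster in centroid
column order and raise a `tie_flag` — a deterministic rule chosen
because the published description is silent on ties.

Because the classifier uses ranks only, any strictly increasing
transform of a sample's expression (log, scaling) leaves every
coefficient and every assignment unchanged; this is tested, and it also
means the classifier is insensitive to whether a cohort was
log-transformed upstream. Scoring is not rank-based, so there the
transform state matters and is the caller's responsibility.

Classification operates on the signature gene universe by default but
accepts any centroid gene list, since microarray coverage differs from
RNAseq. Deriving the cluster system de novo by consensus clustering is
out of scope: centroids are an input, or are computed from a labelled
reference cohort with `compute_centroids()`.

## Single-cell rules

Positivity is strictly greater than the threshold (default 0), so exact
zeros are negative — the "expression > 0 scored positive" convention of
droplet-free single-cell census analyses. A cell is *immune* if any
immune marker (default PTPRC) is positive; *tumour* if all tumour
markers (default SOX9 and EGFR) are positive and no immune marker is;
*ambiguous* if both rule sets fire; *other* otherwise. Ambiguous cells
are excluded from compartment statistics but counted and reported —
exclusion is the conservative reading of a rule conflict. Two presets
are shipped (`sox9_egfr`, `sox2_egfr`) because both tumour-marker pairs
appear in the GBM single-cell literature; the package does not
adjudicate between them.

The immunosuppressive burden of a cell is the number of distinct genes
of an immunomodulatory panel (checkpoint receptors and ligands, TGFB
family, HLA-G pathway, adenosine pathway; see
`immunosuppressive_panel()`) expressed above the threshold. Burden is
monotone non-increasing in the threshold by construction.

Heatmap ordering uses complete-linkage agglomerative clustering on
Euclidean distances of the **untransformed** values. Complete linkage
is the default of the common heatmap tools this display emulates; the
distance and the untransformed scale are the defining choices, and any
log-scaling applied to heatmap colours is display-only.

## Two-group comparison

`median_split()` sends samples strictly above the cohort median to the
high group and at-median samples to the low group; with an even number
of distinct values this yields the even split (107/107 for a
214-sample cohort) that published median-split analyses imply.

`mann_whitney()` reports the $U$ statistic of the first group (pairs
with $a_i > b_j$, ties counted half) and a two-sided p-value. Exact
mode enumerates the permutation null and requires tie-free data with
$n_a + n_b \le 25$; otherwise the tie-corrected normal approximation
with continuity correction is used, and `auto` picks between them.
Published figure panels typically report unadjusted per-gene p-values,
so `compare_features()` defaults to no multiple-testing adjustment;
Benjamini–Hochberg adjustment is available and reported in a separate
column.

# The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; they are first-class, tested code.

**Bulk cohorts.** Signature gene $g$ of cell type $t$ in a sample of
cluster $c$ is drawn as
$\exp(\beta_g + \ell_c(t) + \varepsilon)$, with gene baselines
$\beta_g \sim N(2, 0.5)$ fixed by the seed, cluster infiltration levels
$\ell_c(t) \ge 0$ on the log scale, and
$\varepsilon \sim N(0, \texttt{noise\_sd})$. Background genes omit the
cluster term. Log-normal signal with additive log-scale effects gives
positive, right-skewed expression and a stable rank structure for the
Spearman classifier. The default two-cluster preset contrasts an
immune-hot cluster (lymphoid/cytotoxic levels 2.0, myeloid 1.0) with an
immune-cold cluster (0.2 / 0.6): the profiles differ in *shape*, not
just overall level, because a uniform shift would leave ranks — and
hence the classifier — without signal. Defaults `n_samples = 40` and
`noise_sd = 0.2` define the standard recovery experiment (train
centroids on half, classify the held-out half).

**Single-cell mixtures.** Cells are assigned to populations by
multinomial sampling; each marker or panel gene is expressed with its
population's probability times $(1 - \texttt{dropout\_rate})$, and
expressed genes receive a log-normal magnitude. The default emulates a
GBM single-cell census of 3589 cells with tumour
(SOX9+/SOX2+/EGFR+), immune (PTPRC+, myeloid-marker-rich) and neuronal
populations in proportions 757:1527:1305, immune panel probabilities
exceeding tumour ones, and the HAVCR2/LGALS9 checkpoint pair
co-expressed in immune cells at 92% (either) / 60% (both).

Two deliberate modelling choices: (i) those pair percentages are **not
reachable with independent Bernoulli genes** ($p_A + p_B = 1.52$ with
$p_A p_B = 0.60$ has no real solution), so correlated pairs are drawn
from the 4-category joint distribution \{both, A only, B only,
neither\} with the either-only mass split evenly; pair probabilities
are final observed-expression probabilities and dropout is not applied
on top of them. (ii) The default `dropout_rate` is 0: the positivity
rules operate on the observed matrix exactly as the census convention
does, and dropout is an explicit robustness dial rather than a default
distortion. Values are continuous magnitudes, not counts, because every
downstream rule is threshold-based; a `poisson_counts` flag rounds
through a Poisson draw when integer counts are wanted.

What the simulations do **not** model: realistic zero-inflated
negative-binomial count distributions, batch effects, doublets, and
gene–gene correlation beyond the cluster/population structure and the
configured pairs. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under its stated assumptions, not
its performance on any particular real cohort.

# Numerical and degenerate-input choices

* Gene identifiers match case-sensitively after whitespace trimming; no
  alias mapping (alias resolution is dataset-specific).
* Duplicate gene rows collapse by mean — deterministic and
  order-independent; duplicate *sample* identifiers are fatal.
* `NA`/empty cells parse to missing, never zero: microarray tables
  distinguish absent from unexpressed.
* Constant genes z-score to all-zero rows with a warning; a constant
  vector in a correlation is an error, not an `NA` that silently
  propagates.
* Clustering treats missing values as zero with a warning, matching the
  untransformed-counts setting; a single-item axis returns a trivial
  one-leaf result.
* All simulation randomness flows from one explicit integer seed
  through R's generator; identical config and seed give byte-identical
  output.

# Validation problem sizes

The shipped tests validate Spearman's coefficient against the
rank-difference formula on 200 tie-free vectors, the exact Mann–Whitney
p against full labeling enumeration for all group sizes up to 6, and
the clustering merge heights against a naive $O(n^3)$ agglomeration on
50 random 8×5 matrices. Recovery experiments use 10 seeds at the
default bulk conditions (40 samples, noise 0.2) and 10 seeds of
500-cell simulations at dropout 0; null calibration uses 2000
Mann–Whitney replicates at $n = 20/20$; co-expression consistency uses
a 13 000-cell simulation yielding ≥ 5000 immune cells. These sizes keep
the whole suite fast while leaving the Monte-Carlo tolerances (±1.5 and
±2 percentage points for the pair percentages; type-I error in
[0.035, 0.065]) comfortably wider than the sampling noise.

# Known limitations

* The scoring formula underlying published immune heatmaps is not fully
  specified upstream; both shipped methods are reasonable readings, and
  results should state which was used (the run log records it).
* Nearest-centroid assignment is forced-choice: every classifiable
  sample gets a cluster, with no confidence measure beyond the rho
  margin visible in the per-cluster columns.
* The marker rules are deliberately minimal (2–3 genes); they are not a
  general cell-type annotation method and will misassign rare
  populations that violate the marker assumptions.
* Exact Mann–Whitney mode refuses ties; tied data always use the
  corrected normal approximation, which is approximate for very small
  groups.
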