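# senesig

Cellular senescence — stable cell-cycle arrest with an inflammatory
secretory phenotype — accumulates with organismal age, but senescent cells
remain a minority in every tissue and express different gene programs in
different cell types. No single marker gene (not even *Cdkn2a*/p16) reliably
identifies them in single-cell RNA-seq, where dropout makes the presence or
absence of individual transcripts noisy. **senesig** discovers
cell-type-specific senescence signatures directly from age-annotated
single-cell UMI counts and uses them to score cells and spatial spots for
senescence burden. It is aimed at anyone analysing aging or disease
single-cell/spatial datasets who needs per-cell senescence calls rather
than bulk enrichment.

## What it computes

**Age-dynamic genes.** For each tissue and cell type, the proportion of
cells positive for a gene (at least one UMI) is computed in a young and an
old baseline. Each gene receives a gene age-dynamic (GAD) score — a sum of
piecewise weighted metrics that rewards genes rare in young cells
(`young(x)`), present in a minority of old cells (`old(x)`), with a large
absolute gain (`gain(x)`) and a high old/young ratio capped at 2.5
(mouse), or a positive positivity trend over 10-year age bins plus terms
rewarding peaks near the oldest sampled bin (human). Significance comes
from a permutation null that reshuffles each gene's positive cells across
the population, preserving per-gene totals and the matrix's sparsity.

**Signature discovery.** Dynamic genes are binarized in aged cells
(mice > 21 months, humans ≥ 48 years). Every gene pair's Pearson
correlation of binary vectors (the phi coefficient) is kept only if
`r > 0` and `r` exceeds the 99th percentile of 500 per-pair permutations
by more than 0.05. Louvain clustering of the resulting network yields
*hubs*: communities of co-positive genes. Clusters with fewer than 5 genes
are dropped, as are genes with fewer than `ln(n)` within-cluster edges. A
gene's final within-hub degree is its *importance* weight.

**Signature comparison and universal panels.** Hubs are compared by
importance-weighted cosine similarity and by the hypergeometric overlap
survival function against the expressed-gene background. Genes
overrepresented across many hubs are found with a Poisson-binomial
generating function `G(x) = prod_i (1 - p_i + p_i x)`, `p_i = |S_i|/N`,
expanded by convolution into the exact distribution of a gene's membership
count, with BH correction across genes.

**Scoring.** A cell's score for a hub `S` is
`mean(Z[i, S]) - mean(Z[i, BG])`, where `BG` is a background set sampled
per signature gene from its mean-expression bin (25 bins, 50 controls per
gene), `Z` is the optionally binarized count matrix, and signature genes
are optionally amplified by their importance. Cells scoring above
`mean + 3*sd` of their stratum's distribution are called senescent;
outlier calls are merged across hubs into a per-population burden.

**Spatial.** Visium-style spots are filtered (≥ 1000 detected genes),
normalized to 10,000 counts, log-transformed, scored without binarization
or importance, and outlier spots tested for spatial clustering with
Moran's I under inverse-Euclidean-distance weights truncated at distance 3.

A seeded synthetic-data generator (`simulate_counts()`,
`simulate_spatial()`) reproduces the structure these methods assume —
age-stratified populations with minority senescent subpopulations
co-expressing planted programs — so the whole pipeline is testable without
any external download.

## Worked example

Discover and use a signature on synthetic data (20k-gene runs behave the
same; 5k genes keeps this example quick):

```r
library(senesig)

sim  <- simulate_counts(sim_spec(n_genes = 5000, n_cells_per_age = 1000, seed = 42))
dyn  <- find_dynamic_genes(sim$data, species = "mouse", n_perm = 200, seed = 42)
coll <- build_signatures(sim$data, dyn$gene[dyn$dynamic], species = "mouse",
                         tissue = "lung", cell_type = "fibroblast", seed = 42)
coll
#> <hub_collection> 1 hubs, background: 5000 genes
#> <hub fibroblast_0> mouse/lung/fibroblast — 15 genes (top: g00356, g00634, ...)

head(dplyr::arrange(dyn, empirical_p), 3)[, c("gene", "x_young", "x_old", "gad", "empirical_p")]
#>   gene   x_young x_old   gad empirical_p
#> 1 g00356     1.1  11    5.5   0.0000012
#> 2 g00634     1.7  10.9  5.5   0.0000012
#> 3 g00899     1.5  10.4  5.5   0.0000012

sc    <- score_all_cells(sim$data, coll$hubs[[1]], strata = "cell_type",
                         params = score_params(seed = 42))
calls <- call_outliers(sc, mode = "per-stratum")
senescence_burden(calls[, c("cell_id", "outlier")],
                  groups = sim$data$cell_meta[, c("cell_id", "age")])
#>     age n_cells n_outliers burden
#> 1     3    1000          8  0.008
#> 2    24    1000        109  0.109
```

The 55 dynamic genes (of 4162 tested) include all 15 planted program genes;
the emitted hub recovers the planted program exactly (Jaccard 1.0). The
top genes rise from ~1% positivity in young cells to ~11% in old cells and
reach the maximal GAD of 5.5 (1 + 1 + 1 + capped ratio 2.5). Scored
against the hub, 0.8% of young cells but 10.9% of old cells exceed the
`mean + 3*sd` threshold — matching the planted senescent fractions (1% and
10%) with sensitivity 0.97 and no false positives.

A command-line wrapper over the same functions is installed at
`system.file("cli", "senesig.R", package = "senesig")` with subcommands
`simulate`, `dynamic-genes`, `build-signatures`, `compare`, `universal`,
`score`, `outliers`, and `spatial`.

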