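---
title: "Models and methods behind senesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind senesig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in senesig, the
assumptions they make, the tunable parameters and their defaults, the
design choices taken where the design was genuinely open, and what the
synthetic fixtures do and do not demonstrate about real data.

## The positivity model

Everything upstream of scoring operates on *positivity*: a cell is
positive for a gene when it carries at least one UMI. Working on the
binary layer sidesteps two properties of UMI counts that defeat
differential-expression approaches for senescence: dropout (a senescence
gene may be detectable in only a fraction of the cells that express it)
and the fact that senescent cells are a minority whose signal is diluted
in population means. The model's core assumption is that the *proportion*
of positive cells for a senescence marker rises with organismal age while
remaining small — a gene expressed in 1% of young and 10% of old cells is
a far better candidate than one expressed in 60% of all cells that rises
slightly.

## The gene age-dynamic (GAD) score

For mouse data, populations are stratified by tissue and cell type. The
young baseline is the 3-month group when it has ≥ 200 cells, otherwise
3-month and 1-month cells aggregated (used down to a single cell, with a
log message, since no lower bound is defined for the aggregated baseline);
the old baseline is 30 months when it has ≥ 200 cells, otherwise 24
months. 18- and 21-month cells are never used as an old fallback. Zero
young positivity is imputed as `1/n` so the old/young ratio stays finite;
an imputed proportion can never exceed a non-imputed one since `1/n` is
the smallest observable proportion.

The score is a sum of piecewise weighted metrics of the percent positive
(0–100 scale):

* `old(x)`: logistic `1/(1+e^(-2x))` for `x ≤ 3`, `1` for `3 < x ≤ 20`,
  `-x/4 + 6` beyond — old positivity between 3% and 20% is ideal; high
  positivity is penalized because ubiquitous genes are not markers.
* `gain(x)`, with `x = x_old - x_young`: `x/5` below 5, `1` between 5 and
  15, `-x/5 + 4` above.
* `young(x)`: `1` below 5, `-x/2 + 3.5` otherwise — constitutive
  expression in young cells disqualifies a marker.
* `ratio(r) = min(r, 2.5)`.

The human score replaces the ratio with three terms suited to binned ages
(10-year bins indexed 8…88): `dMax` penalizes genes whose positivity peaks
long before the oldest sampled bin, `aMax` penalizes populations whose
oldest bin is younger than 38, and the per-year regression slope of
positivity (in percentage points) enters with weight 5. A gene must have a
positive slope to be a candidate at all. Eligibility of a human population
requires, within one dataset, three bins with ≥ 100 cells or a young
(≤ 28) and an old (≥ 58) bin, plus a bin ≥ 48 — so that an old baseline
exists and a trend is estimable. When no bin ≤ 28 exists, the young
proportion is extrapolated to 18 years by least squares and floored at
`1/n` of the youngest bin.

Two choices here were genuinely open:

* **Direction of the peak-distance term.** Taken literally, the printed
  difference (peak age minus oldest age) can never reach the penalty
  branch, because the peak cannot lie beyond the oldest sampled bin. We
  implement the corrected direction (oldest minus peak), which activates
  the penalty for genes peaking ≥ 50 years before the oldest bin; the
  literal form remains available via `dmax_literal = TRUE`.
* **Ties for the peak bin** go to the oldest tied bin, favouring genes
  whose positivity is sustained into old age — consistent with the
  score's intent.

## The permutation null

Significance is assessed against a pooled null built by reshuffling, per
gene, the assignment of that gene's positive cells across all cells of
the population — preserving each gene's total positive count, and hence
the exact sparsity structure the score is sensitive to. Implementation
note: for a single gene this reshuffle induces a (multivariate)
hypergeometric distribution of per-group positive counts, so the null is
sampled directly from that distribution rather than by materializing
permuted matrices; the two procedures are distributionally identical and
the count-preservation invariants are asserted in the test suite. For
human populations the same scheme applies with bin membership held fixed;
a within-bin shuffle would preserve every bin's positive count and
reproduce the observed score exactly, so it cannot serve as a null.

All null GAD values of a population are pooled (1000 permutations ×
genes tested by default) and a gene's empirical p-value is
`(1 + #{null ≥ observed}) / (1 + n_null)`, the standard +1-corrected
estimator that can never be exactly zero. The calling threshold defaults
to `alpha = 0.01`; the null-comparison threshold was not pinned down
numerically in the score's original description, and 0.01 on the pooled
empirical p is the natural reading that also keeps the expected number of
false dynamic genes near 1% of those tested.

## Co-positivity networks and hubs

Dynamic genes are binarized over aged cells only (mice > 21 months,
humans ≥ 48 years; subsets under 100 cells are skipped). Pearson's
correlation of two binary vectors is the phi coefficient and is computed
from the 2×2 margins. The per-pair null reshuffles one gene's vector —
sufficient to break the association — making the co-positive count
hypergeometric; 500 draws are taken and a pair is kept only when `r > 0`
and `r` strictly exceeds `q99(null) + 0.05`. The 99th percentile uses
linear interpolation between order statistics (R's default type 7). Ties
at exactly the threshold are not kept.

Louvain clustering (resolution 1, seeded) partitions the kept-edge graph.
Clusters under 5 genes are removed; genes with fewer than `ln(n)`
within-cluster edges are pruned in a single pass followed by one size
re-check (iteration to a fixed point is available but off by default —
the cleanup is described as one step). The natural log is the default
base, configurable. A gene's importance is its within-hub degree after
pruning.

## Signature comparison and the universal panel

Cosine similarity embeds each hub as its importance vector over the union
of gene lists; hypergeometric overlap uses the survival function
`P(X ≥ |A∩B|)` with the dataset's expressed genes as the universe.
Pairwise overlap p-values feeding the similarity network are
Bonferroni-corrected (as used for network figures); BH is used elsewhere.
The background universe must always be supplied or stored explicitly —
cross-dataset collections never silently union their genes.

Overrepresentation across `k` hubs uses the Poisson-binomial law of a
gene's membership count under uniformly random signatures of the observed
sizes. The generating function is expanded by iterative convolution
(`O(k²)`, exact in double precision for the relevant `k`); upper-tail
probabilities are summed directly from the PMF rather than via `1 − CDF`
to avoid cancellation. The printed tail convention is `P(X > m)` — which
assigns p = 0 when a gene is in every set; the conventional `P(X ≥ m)` is
available via `tail = "geq"`. BH correction ranks only genes observed in
at least one hub; unobserved genes are assigned `q = 1` outright, since a
gene never observed cannot be overrepresented. A Monte-Carlo permutation
version of the same test exists (`permutation_overrepresentation()`) and
agrees with the analytic tail in rank order; the analytic form is the
default because it is exact and fast.

## Scoring

Scoring follows the bin-matched module-score family: per-gene means over
all cells of the stratum, genes ranked and cut into `n_bins = 25`
equal-size bins (ties broken by rank order), `ctrl_size = 50` background
genes sampled per signature gene from its bin excluding all signature
genes (with replacement, logged, when a bin is too small). The background
is a *set* — a gene drawn for two signature genes counts once. Counts are
binarized by default (the binary senescence state that the networks were
derived from); binarization requires the raw layer, whereas the
normalized-log flavor (used for spatial spots) leaves values continuous.
Importance amplification applies to signature genes only. Gene means for
bin construction use the raw values, since bins are built before the
optional binarization step.

Outliers are strictly above `mean + 3·sd` of their stratum's score
distribution; spatial spots must exceed both their own sample's and the
pooled threshold (`mode = "both"`). Zero-variance distributions yield no
outliers. Scoring is deterministic given the seed, and scoring a stratum
alone reproduces its rows from the stratified run exactly.

## Spatial autocorrelation

Moran's I is computed with weights `1/d(i,j)` truncated at distance 3 (in
the units of the supplied coordinates, with no rescaling) and zero
diagonal. The accompanying prose and formula for the truncation disagree
in direction; the formula (`d ≤ 3` keeps weight) is implemented, since
zeroing *near* neighbours while letting `1/d` diverge at small distances
would contradict the stated maximum-distance intent. Coincident spots get
weight zero with a warning. The analytic p-value `1 − Φ(I)` is
implemented exactly as the statistic is defined, but note it treats the
raw I as a standard normal deviate without standardization; the
permutation p-value (999 label shuffles, `p_method = "permutation"`) is
the recommended mode and is what the spatial report examples use.

## The synthetic-data generator

`simulate_counts()` generates counts as Bernoulli positivity × (1 +
Poisson magnitude). A full negative-binomial hierarchy is deliberately
not used: every statistic in the pipeline consumes the binary layer, so
realism beyond positivity would add parameters without adding test
power. Background per-gene positivity rates are Beta(0.3, 6) (right
skewed, mean ≈ 5%, matching typical UMI sparsity). The default study
conditions are 20,000 genes, 1,000 cells per age group (3 and 24
months), a 15-gene planted program co-positive at rate 0.9 within
senescent cells and 1% positive elsewhere, and senescent fractions of 1%
(young) and 10% (old) — a minority that accumulates with age. Ground
truth is emitted as a sidecar table so tests never reach into generator
internals.

What passing tests on these fixtures shows: the pipeline recovers planted
co-positivity structure at realistic sparsity, its null calibration is
correct, and its thresholds behave as specified. What they do not show:
robustness to batch effects, ambient RNA, doublets, cell-type
misannotation, or confounding between age and library depth — none of
which the generator emulates.

## Problem sizes and numerical choices

The test suite and the acceptance script run the end-to-end recovery at
the default 20,000-gene fixture with the GAD null at 200 permutations
(the calling decisions stabilise well below the 1000-permutation default
on these fixtures) and the per-pair edge null at its full 500. Exact
oracles (exhaustive enumeration of hypergeometric draws, 2^k inclusion
patterns, dense Moran evaluation) are kept at sizes where enumeration is
feasible (N ≤ 12, k ≤ 12, ≤ 100 spots). Degenerate inputs — constant
gene vectors, zero-variance score distributions, empty edge sets,
all-distant spot sets — are defined errors or logged skips, never silent
results.

## Known limitations

* Only gain-of-expression markers are discovered; genes downregulated in
  senescent cells are out of scope by design.
* The analytic Moran p-value follows the score's printed definition and
  is anticonservative relative to the standardized test; use the
  permutation mode for inference.
* Per-pair edge permutation is `O(pairs × n_perm)`; for very large
  dynamic-gene sets a pooled-null approximation (one null per gene,
  shared across its pairs) is available behind a flag but is off by
  default because per-pair nulls are the specified behaviour.
* Hub serialization uses this package's JSON schema; no interchange
  format for senescence signatures exists.
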