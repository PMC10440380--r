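---
title: "Models and design choices in wdliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in wdliver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdliver)
```

wdliver analyzes a 2×2 diet-by-time liver transcriptome experiment —
low-fat diet (LFD) vs western diet (WD), 1 vs 40 weeks of feeding, in
female and male mice — together with a single-cell reanalysis that maps
diet-responsive genes onto liver cell types. This vignette explains the
statistical models, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the
design was genuinely open.

## Bulk model

### Normalization

Counts are quantile normalized: each sample's sorted value vector is
replaced by the row-wise mean of all samples' sorted vectors, with ties
receiving the mean of the reference values at their rank positions
(`quantile_normalize()`, backed by limma). Downstream testing is on
`log2(x + 1)`; the pseudocount of 1 is the conventional guard for zero
counts and maps a zero to exactly 0 on the log scale.

Quantile normalization assumes samples share a common distribution. When
a large asymmetric fraction of the transcriptome genuinely shifts — as in
our simulations that plant strong interaction effects in 10% of genes —
the forced common distribution leaks a small compensatory distortion into
unaffected genes. In such regimes the interaction screen's realized false
discovery proportion can exceed the nominal BH level even though the
per-gene tests are exact (we observe roughly 0.25 at a nominal 0.1 on the
most extreme synthetic configuration, while sensitivity stays above
0.95). This is a property of quantile normalization itself, not of the
tests; the FDR-calibration checks therefore simulate directly on the log2
scale, and on real data the practical safeguard is the fold-change gate
that accompanies every DE call.

### Per-timepoint differential expression

At each timepoint the WD and LFD groups (sexes pooled as replicates, a
`by_sex` option stratifies instead) are compared per gene with Welch's
unpaired t-test on log2 values. The published analysis reported only an
"unpaired t-test"; Welch's form is the robust default when group
variances need not be equal, and with 8 vs 16 animals per pooled group
the cost in degrees of freedom is negligible. A gene is called *up* when
`fold_change >= 2` and BH `q <= 0.1`, *down* when `fold_change <= 0.5`
and `q <= 0.1`. Both comparisons are inclusive, matching the "≥ / ≤"
phrasing of the criteria they implement. Genes with zero variance in both
groups cannot be tested: they are reported with `p = NA`, excluded from
the BH ranking, and called `ns` with a warning.

BH correction is run separately per timepoint: each screen is described
and interpreted independently, and a joint correction would couple the
1-week call set to the 40-week data.

### The diet × time interaction screen

The quantity of interest for "progressive" genes is the interaction term
of a fixed-effects 2×2 ANOVA on log2 expression. We compute it as a
model comparison: `F = (SSE_additive − SSE_full) / (SSE_full / (N − 4))`
with df (1, N − 4), where the full model fits the four cell means and the
additive model fits diet + time. On balanced designs this reduces to the
textbook `MS_interaction / MS_within` decomposition (and equals the
squared t statistic of the difference of diet contrasts — an identity the
test suite checks numerically); on unbalanced designs, such as the
study's 4 LFD vs 8 WD mice per sex, it remains the correct
interaction-last test. The implementation is vectorized with residual
projection matrices shared across genes and verified against `stats::aov`
gene by gene.

Progressive genes are selected from the interaction table with strict
fold-change gates — `log2fc_1wk > 0` and `log2fc_40wk > 1` (fold change
> 2) — because those criteria are stated with strict inequalities, while
q uses the inclusive `q <= 0.1` ceiling (or 0.01 under the
`interaction_strict` preset that mirrors the FDR < 1% cutoff applied to
the merged early/late gene set).

### Cluster summaries

For the heatmap stage each gene is reduced to four per-group geometric
means, `2^mean(log2(v + c)) − c` floored at 0 (with `c = 0` a zero value
sends the geometric mean to 0, which is the mathematically standard
behavior). Genes are clustered with Lloyd's k-means (k-means++ seeding,
best of `n_init = 10` restarts by inertia) on row-standardized profiles;
k defaults to 8. Row standardization is exposed as a flag: relative
heatmaps color by row, so clustering the shape rather than the level of
a profile is the behavior users expect, but it is not certain the
original analysis did so. Cluster labels in the source figures are not
derivable from any stated rule, so clusters are relabeled 1..k by
descending size (ties broken by the smallest member gene ID), which makes
labels deterministic for a given seed. Each cluster is summarized per
group by the median of its genes' geometric means; the methods text and
the figure legend disagree between "summation" and "median", and we take
the legend (the more specific statement) as the default while exposing
`stat = "sum"` and `"mean"`.

## Single-cell model

The reanalysis pipeline is the de facto standard: per-cell scaling to
10,000 counts, log1p, top-2,000 genes by dispersion, PCA to 30
components, then Louvain community detection on a 15-nearest-neighbor
graph (a k-means mode exists for dependency-light runs and fixed k).
The "normalized UMI" quantity that feeds the marker gate is the per-cell
scaled value *without* log transform, since the `> 1.0` threshold is
stated on normalized UMIs, not their logarithm.

A gene is a candidate marker of a cluster when its mean normalized UMI
there exceeds `umi_min = 1.0`, the one-sided Wilcoxon rank-sum test
against all other cells passes BH `q <= 0.05` (corrected within cluster
over all genes, keeping the BH universe fixed), and its log2 fold change
vs the rest is at least 1. The published criteria name "UMI > 1.0, with a
significant fold change" but no test or cutoffs; the Wilcoxon/BH/log2FC
triple is a declared engineering choice, with every threshold exposed.
"Uniquely expressed" is enforced as: candidate in exactly one cluster
*and* mean normalized UMI at most `umi_other_max = 1.0` in every other
cluster. The foreign-cluster ceiling is deliberately a separate parameter
from `umi_min`: if the same value played both roles, raising the
own-cluster gate would loosen the exclusion, and the intuitive
monotonicity — a stricter gate can only shrink the catalog — would fail.
Fold-change ratios carry an `eps = 1e-9` guard against division by zero.
Cell-type names are user-supplied labels; the package never infers
biological identity.

Bulk genes are assigned to the cell type whose catalog contains them;
genes in no catalog are `unassigned`, and genes absent from the
single-cell gene universe are distinguished with reason `not_measured`.
Percentages are reported over the queried universe by default, with an
`assigned`-denominator option, because published percentage statements of
this kind are ambiguous about their denominator and the two readings can
differ by a factor of two.

## Enrichment

Over-representation uses the one-sided hypergeometric tail against
user-supplied GMT collections intersected with a declared background — a
transparent stand-in for web-service enrichment tools, not a
reimplementation of any of them. Preranked GSEA uses the weighted
running-sum enrichment score (hits add `|score|^weight` normalized over
in-set mass, default weight 1; misses subtract `1/(N − K)`), with
significance and NES from gene-label permutations (the only permutation
scheme available to a preranked analysis): `p` is the add-one-smoothed
fraction of same-sign permutation scores at least as extreme, and
`NES = ES / mean |ES_perm|` over same-sign permutations. The default of
1,000 permutations bounds the resolution of `p` at about 1e-3.

## The synthetic-data generator

Bulk counts follow a negative binomial with shared dispersion (the
standard RNA-seq noise model; the generative model was otherwise
unspecified). The default design mirrors the study: two sexes, 4 LFD and
8 WD mice per sex per timepoint, so 48 samples. Baseline log2 means are
uniform on [3, 10]; main-effect genes shift by ±1 log2 at both
timepoints; interaction genes shift by +2 log2 only in the WD 40-week
cell, mimicking genes progressively induced by the diet; per-sample
library factors are log-normal with sd 0.2 to give quantile normalization
something to do. Effect placement is random unless an explicit gene list
is supplied — the linked bulk/single-cell fixture plants the single-cell
marker genes as bulk interaction genes so end-to-end cell-type recovery
has a known answer.

Single-cell UMIs are negative binomial around cell-type expected
fractions: cell totals are Poisson around `library_size_mean`, each type
multiplies its disjoint marker block by `marker_fold` (8 by default).
Marker genes sit on a low common baseline (`marker_baseline_norm`, 0.25
normalized units at the 10⁴ scale) so that outside their own type they
are near-silent — the structure cell-type-unique genes have in real
tissue, and the regime in which a uniqueness rule with an absolute
normalized-UMI ceiling is satisfiable at fixture gene counts.

What the generator does **not** emulate: gene–gene correlation beyond
shared library factors, mean-dependent dispersion trends, ambient RNA,
doublets, batch structure, or sex-specific effects (sexes are generated
but exchangeable). Passing recovery tests on these fixtures demonstrates
that the machinery is correct and calibrated under its stated model, not
that real-data effect sizes will be recovered at the same rates.

## Numerical and testing choices

- Degenerate inputs: zero-variance genes give `p = NA` everywhere and are
  excluded from BH ranking; empty clusters summarize to NaN with a
  warning; zero-total cells are an error at normalization.
- BH ties are resolved by stable ordering, and k-means / Louvain / GSEA
  permutations all run under caller-supplied seeds, so identical
  configuration reproduces byte-identical outputs.
- The FDR-calibration suite simulates 200 replicates of 2,000 genes with
  6 samples per cell and Gaussian log2 noise (sd 0.5), 10% of genes
  carrying a 1.0-log2 interaction. At q ≤ 0.01 the theoretical BH bound
  (`q·m0/m = 0.009`) is nearly attained, so the 200-replicate average is
  assessed within its Monte-Carlo standard error rather than as a sharp
  inequality.
- Problem sizes in the tests (hundreds of genes, tens to a hundred cells
  per type) are chosen so the full suite runs in well under a minute of
  compute per file while leaving planted effects comfortably detectable;
  the acceptance-scale experiments use the sizes stated above.
- Gene identifiers are opaque strings throughout; no identifier mapping
  is attempted, and the bulk and single-cell analyses are linked purely
  by shared IDs.

## Known limitations

- No empirical-Bayes variance moderation or count-model DE (limma-voom /
  DESeq2-style analysis is intentionally out of scope): with very few
  replicates per group the Welch test is noticeably less powerful than
  moderated alternatives.
- Quantile normalization's compositional distortion under massive
  asymmetric DE, discussed above.
- The single-cell pipeline performs no doublet removal, ambient-RNA
  correction, or batch integration; it assumes a single, reasonably clean
  UMI matrix.
- Marker uniqueness with an absolute normalized-UMI ceiling is sensitive
  to the number of genes in the matrix (the ceiling is expressed in
  counts-per-10,000 units); analyses on heavily filtered matrices should
  revisit `umi_other_max`.
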