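---
title: "Co-expression modules from multi-batch compendia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression modules from multi-batch compendia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

## The analysis

`coexmod` builds a *condition-independent* weighted gene co-expression
network from a compendium of expression experiments pooled across many
conditions (the motivating use case is a bacterial microarray compendium:
dozens of samples from heterogeneous stress and knockout experiments,
merged into one genes x samples log-ratio matrix with batch labels). Genes
that covary across conditions are grouped into modules; each module is
summarized by an eigengene; modules are screened for reproducibility,
associated with externally derived stress gene lists, and mined for hub
genes and candidate regulators. The stages are:

1. **Similarity.** Biweight midcorrelation (bicor) between all gene pairs,
   taken in absolute value: `S_ij = |bicor(i, j)|`. The network is
   *unsigned* so that positively and negatively co-regulated pairs are
   treated alike. Bicor centers each vector at its median and downweights
   observations by Tukey's biweight, `w = (1 - u^2)^2` for
   `u = (x - med x) / (9 MAD x)` and `w = 0` beyond `|u| = 1`, so a single
   gross outlier (which a pooled compendium will contain) cannot dominate
   the correlation the way it can with Pearson. MAD is used without the
   Gaussian consistency constant; it cancels in the correlation. A vector
   with zero MAD (heavily tied data) falls back to mean/SD centering for
   that vector, and the fallback is recorded.
2. **Soft threshold.** Adjacency `a_ij = S_ij^beta`, with `beta` the
   smallest integer power at which the network's connectivity distribution
   is approximately scale-free: connectivities are binned into 10
   equal-width bins and `log10(frequency)` is regressed on
   `log10(mean k)`; the signed fit index is `-sign(slope) * R^2` and the
   selection target is 0.9. When no power on the grid reaches the target
   (common for small simulated designs, whose planted equal-size modules
   are deliberately *not* scale-free), the power maximizing the index is
   returned with a machine-readable warning flag rather than an error.
3. **Topological overlap.** `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 -
   a_ij)` with `l_ij = sum_u a_iu a_uj`; `1 - TOM` is the clustering
   dissimilarity. TOM rewards shared neighborhoods, which sharpens module
   boundaries relative to raw adjacency.
4. **Module detection.** Average-linkage hierarchical clustering of
   `1 - TOM`, cut by a dynamic hybrid procedure (below), minimum module
   size 20 genes. Genes not assigned to any module are labeled 0 ("grey").
5. **Eigengenes and merging.** A module eigengene (ME) is the first
   principal component of the module's z-scored expression, unit norm over
   samples, with its sign fixed to correlate non-negatively with the
   module's mean profile. Modules whose eigengenes cluster below height
   0.2 on the `1 - cor(ME_i, ME_j)` scale (eigengene correlation above
   0.8) are fused iteratively, the fused module keeping its largest
   constituent's label, until no eigengene pair is closer than the cut.
6. **Stability.** Half of the samples are drawn without replacement, the
   similarity and adjacency are rebuilt on the half-sample, and each
   gene's intramodular connectivity is recomputed with module membership
   frozen at the full-data partition. Per module, the resampled and
   full-data connectivity vectors are correlated (Pearson); a module is
   called stable when the mean correlation over resamples exceeds 0.7.
7. **Downstream.** Hub = the gene maximizing intramodular connectivity
   among genes with own-module kME above 0.8; hypergeometric tests
   associate modules with stress gene lists and annotation terms
   (two-sided: enrichment and depletion tails); transcription factors are
   ranked by their bicor with the module hub; uncharacterized hubs are
   annotated by the enriched terms of their close topological neighbors
   (TOM above 0.01), the top term being the smallest significant
   enrichment p.

## The dynamic hybrid cut, as implemented here

The tree cut is an independent implementation of the dynamic hybrid idea,
contracted on planted-structure recovery rather than bit-identity with any
reference. It has two stages.

**Branch finding.** The dendrogram is first cut at 99% of its maximum
merge height. Because the final merge always lies above that line, the cut
alone would shatter even a perfectly homogeneous tree, so sibling subtrees
are *joined back* whenever their joining height clears neither side's
internal structure by a minimum gap — a flat tree therefore stays in one
piece, while late, isolated attachments (noise genes in TOM space join
near the top) are left outside every branch. Each surviving component of
at least `min_cluster_size` genes is then split recursively: a node is
divided when both children hold at least `min_cluster_size` genes and the
joining height exceeds the children's internal merge heights by the
minimum gap; when only one side is large enough and the small side
attaches well above the large side's internal structure, the small side is
trimmed (its genes become unassigned, recoverable by stage two) and
descent continues. Gaps are measured on the absolute dissimilarity-height
scale (TOM dissimilarities live in `[0, 1]`), and `deep_split` in 0..4
maps to minimum gaps of 0.30, 0.20, 0.125, 0.075 and 0.025: a larger
`deep_split` accepts shallower separations and so splits more aggressively.
The default 2 (gap 0.125) cleanly separates factor-driven modules, whose
between-module joins sit 0.15-0.2 above their internal structure at
`beta = 6`, without fragmenting them.

**PAM-like assignment.** Each unassigned gene is given to the cluster with
the smallest average dissimilarity to it, provided that distance is below
the cluster's own mean internal dissimilarity; otherwise it stays grey.
This rescues genuine members trimmed as offshoots while leaving background
genes (average TOM dissimilarity near 1 to everything) unassigned.

A plain fixed-height cut with a size filter (`cut_static`) is kept as a
transparent fallback for debugging.

## Tunable parameters

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `method` | bicor | — | robust to the gross outliers of pooled compendia |
| `beta_grid`, `r2_target` | 1..20, 0.9 | power, fit index | smallest power with scale-free fit 0.9 |
| `n_bins` | 10 | connectivity bins | equal-width binning for the log-log fit |
| `min_module_size` | 20 | genes | smallest module of interest |
| `deep_split` | 2 | 0..4 | gap 0.125 on the dissimilarity scale, see above |
| `max_cut_height` | 0.99 | fraction of max height | removes the top noise joins |
| `merge_height` | 0.2 | 1 − cor(ME) | merge modules with eigengene correlation > 0.8 |
| `stability_fraction`, resamples, threshold | 0.5, 1000, 0.7 | — | half-sampling; tests and examples use 100–200 resamples to keep runs short |
| `kme_min` | 0.8 | correlation | hub eligibility floor |
| `tom_min` | 0.01 | TOM | "close neighbor" floor for guilt-by-association |
| `alpha` | 0.05 | p-value | raw enrichment p; a BH-adjusted column is always emitted so the user can choose |
| `max_missing_frac` | 0.5 | fraction | genes with more missing data are dropped; survivors are median-imputed so correlations are defined on complete data |

TF strength categories follow the 0.8 / 0.5 boundaries (high at and above
0.8, moderate in `[0.5, 0.8)`, low below 0.5); a correlation of 0.78 is
therefore "moderate".

## The synthetic generator and what it does (not) show

`generate_dataset()` plants `n_modules` latent standard-normal factors
over samples; gene `g` of module `m` with loading `l` has profile
`l * f_m + noise_sd * sqrt(1 - l^2) * eps`, so with the default
`noise_sd = 1` the population gene-factor correlation *equals* the
loading. Defaults — 5 modules of 40 genes, loadings uniform in
`[0.8, 0.95]`, one hub per module at loading 0.98, one planted regulator
at 0.9, 100 pure-noise background genes, 60 samples in 3 label-only
batches — describe a compendium with strong, well-separated co-expression
structure at roughly the sample size of the motivating data. When an
inter-factor correlation is requested (to exercise the merge rule), it is
realized *exactly* in sample by Gram-Schmidt construction, so the planted
condition is the stated correlation and not a noisy draw around it.
Outlier cells are multiplied by `outlier_scale` rather than replaced,
preserving sign structure while stressing bicor against Pearson.

The generator deliberately does **not** emulate: batch mean shifts (labels
only; the package inspects batch structure via box plots and classical
MDS but never corrects it), probe-level artifacts or normalization
residuals, scale-free degree structure (planted equal-size modules are
nothing like a power law, which is why the soft-threshold scan on
synthetic data exercises the fallback path), or realistic annotation
sparsity. Passing tests therefore demonstrate that the algorithms recover
the structure they assume, at compendium-like sizes — not that any real
compendium satisfies those assumptions.

## Numerical and convention choices

- **Quartiles** in the batch box-plot summaries use the linear
  interpolation convention (`quantile type 6`), under which the five-number
  summary of `{1,2,3,4,5}` is `(1, 1.5, 3, 4.5, 5)`; box-plot conventions
  differ and this one is stated explicitly.
- **MDS** is classical principal coordinates on Euclidean inter-sample
  distance (double-centered squared distances, eigendecomposition, top two
  axes scaled by root eigenvalues). The motivating analyses name only the
  plotting tool, not the algorithm; classical scaling matches the
  descriptive use and reproduces planar geometry exactly, which the tests
  assert to 1e-9.
- **Diagonals**: adjacency and TOM diagonals are fixed at 1 but excluded
  from all connectivity sums.
- **Identity resamples**: with `fraction = 1` every resample is the full
  sample set in original order; the correlation of a connectivity vector
  with itself is taken as exactly 1 (bypassing floating-point round-trip),
  so the report reads mean 1, SD 0 exactly.
- **Ties** are always broken deterministically and documented: hub ties by
  higher total connectivity then lexicographic gene ID; equal-size modules
  by lexicographically smallest member ID; equal top-term p-values by term
  ID (logged); module colors follow the canonical size-ordered palette,
  extended as `module_N` when exhausted.
- **Universe** for association and enrichment defaults to the network's
  genes (those surviving `qc_filter`), substitutable by any user-supplied
  universe; grey genes stay in the universe but grey is not reported as a
  module by default.
- **Stability connectivity** is adjacency-based (`kWithin` on the
  resampled adjacency); recomputing TOM per resample is a conceivable
  alternative we did not adopt, as the adjacency version is the direct
  reading of "connectivity correlation" and is linear in resamples.
- **Hub criterion**: `kWithin` is primary and total degree only breaks
  ties; combining the two into a single score is underdetermined and the
  tie-break formulation keeps the selection order-invariant.

## Known limitations

- The stability statistic's null baseline is not 0: a half-sample shares
  half its data with the full sample, so even independent-noise
  pseudo-modules score around 0.3. The 0.7 rule sits well above this
  baseline, but the statistic should not be read as a correlation against
  an independent replicate.
- Stability is **not** monotone in module signal strength: at weaker
  loadings the spread of true intramodular connectivity across genes is
  relatively larger and its ordering is reproduced at least as faithfully
  under half-sampling. What separates real modules from noise is the
  margin over the baseline, not the absolute level, and that is what the
  package's tests assert.
- The unsigned network cannot distinguish activation from repression, and
  absolute correlation carries a positive bias under pooling.
- Dynamic-cut results are contract-tested on planted-structure recovery
  (adjusted Rand index at least 0.9 on the default design, checked at
  fixed seeds); branch boundaries on weakly separated real data need not
  coincide with those of other dynamic tree cut implementations.
- Examples and tests run at reduced problem sizes (hundreds of genes,
  100-200 resamples), chosen as the package's standard verification
  design; the algorithms themselves are dense-matrix exact and scale as
  `O(n^2 m)` for similarity and `O(n^3)` for TOM.
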