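---
title: "Two-tier brain reference mapping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier brain reference mapping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `brainstem`, the
reasoning behind every tunable parameter, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the method
left genuine freedom. It states no empirical number that the package's test
suite or acceptance script does not itself compute.

## 1. The mapping model

### Preprocessing

All expression work happens on a log-normalized layer,
`ln(1 + 10^4 * count / cell_total)` (`log_normalize()`, scale factor
10,000). Highly variable genes are ranked by standardized variance: a
robust loess trend (span 0.3, degree 2, symmetric family) of log10 variance
against log10 mean is fit across expressed genes, values are standardized
by the trend-expected SD and clipped at `sqrt(N)`, and the variance of the
clipped values is ranked (`rank_variable_genes()`). Rankings from several
datasets combine by summed rank (`select_consensus_hvg()`, default top
3,000). The reference PCA (`fit_preprocess()`) z-scores HVG rows with a
clip at ±10 SD and takes a truncated SVD (default 50 PCs); the sign of each
loading column is fixed so its largest-magnitude entry is positive, making
the basis bit-reproducible. Queries are projected with the *reference*
mean/SD and loadings (`project_query()`); HVGs missing from a query
contribute 0 after scaling, i.e. are imputed at the reference mean.

*Why no anchor-based integration:* the framework's contribution is its
tiering, confidence filtering and scoring logic, not the projection engine.
Plain reference-basis projection is deterministic and dependency-free; the
cost is that strong query-specific batch structure is not corrected, which
the label-recovery tests quantify (held-out type accuracy ≥ 0.9 under the
simulator's conditions). The module boundary allows an anchor engine to be
slotted in behind `project_query()` later.

### Label transfer

`transfer_labels()` takes each query cell's `k_transfer = 30` nearest
reference cells in PC space and forms a Gaussian-kernel-weighted vote; the
bandwidth is the cell's median neighbour distance, so the kernel adapts to
local density with no free parameter. The prediction score is the winning
label's weight share; ties break lexicographically, as do all ties in the
package.

### Confidence filtering

For each predicted type, the query-wide module score of that type's top-20
reference markers is computed (`confidence_filter()`), and a cell is
*confident* iff its own type's score is strictly greater than 0. The
module score (`module_score()`) is the binned-control scheme: genes are
binned into 24 equal-frequency bins by query-wide mean expression, 100
control genes per signature gene are drawn from the matching bin (seeded),
and the score is mean(signature) − mean(controls). A zero score therefore
means "not expressed above an expression-matched background".

### Region assignment

Each confident cell receives module scores for the three regions
(`assign_region()`): for its predicted type, the (type, region) marker set
where the reference carries one, the global per-region set otherwise;
`predicted_region` is the argmax (ties → forebrain, the lexicographic
first). Two derivation details matter:

- **Global region sets come from region-specific cell types that span
  several regions.** Deriving them from all cells lets region-exclusive
  *type* programs masquerade as regional genes; a cell of any other type
  then scores those sets as pure background shifted by the binned-control
  penalty, and assignment degrades for everyone.
- **Region-specific types confined to one region** (e.g. a
  midbrain-exclusive dopaminergic type) get a home-region set equal to the
  markers of those cells against the whole reference. Regional identity for
  such types is carried by type-restricted regional genes, which is exactly
  what per-(type, region) DEG panels contain in real atlases.

### The two tiers and the gate

`run_two_tier()` chains projection → transfer → confidence → region
against the whole-brain reference, then re-maps the confidently
midbrain-assigned subset against the midbrain reference. Queries with fewer
than 1,000 confident midbrain cells are *refused* (a typed outcome carrying
the count, not an error): below that size a fine-grained midbrain analysis
is not meaningful. The boundary keeps exactly 1,000 (`n >= 1000` passes);
the cutoff is configurable (`min_midbrain_cells`). Tier 2 applies the same
confidence rule with midbrain markers; a switch (`tier2_confidence`)
disables it for sensitivity analyses.

`direct_map()` is the baseline: one-step projection onto a single-region
reference with confidence filtering but no region assignment. Its defining
failure mode — it can only emit its own reference's labels — is asserted
structurally in the tests.

## 2. Fidelity metrics

- **Region specificity** (`neighbor_region_agreement()`): restricted to one
  cell type, each cell's classification probability is the fraction of its
  k = 10 nearest neighbours (Euclidean on the top-50 PCs, self excluded —
  otherwise agreement is inflated by 1/k) sharing its region label; a type
  is region specific when the mean over all its cells strictly exceeds
  0.65. The winning-vote probability is reported alongside
  (`mean_vote_prob`) but flagging uses the self-label fraction, which
  matches the quantity the threshold was defined on. Per-(type, region)
  rows support heatmap-style summaries.
- **Ventral score** (`train_ventral_model()` / `ventral_score()`): a
  500-tree probability random forest (`ranger`, seeded) on the midbrain PC
  coordinates with ventral as the positive class; 20% of cells are held out
  for a validation AUC. The contract is "calibrated probabilistic binary
  classifier on PC features"; any engine meeting the AUC and determinism
  contract could stand behind it.
- **Identity strength** (`identity_strength()`): log2 fold change of every
  gene between the cells predicted as the target type and all other
  predicted cells (de-logged means, pseudocount 1), fed to preranked GSEA
  (`preranked_gsea()`) with the type's top-50 reference markers as the set.
  ES uses hit increments |score| normalized over hits and miss decrements
  1/(N−|S|); the null is `n_perm = 1000` seeded permutations of set
  membership; NES divides by the mean |null ES| of the same sign, and the
  p-value is (1 + #{same-sign null ≥ |ES|}) / (1 + #same-sign null).
- **Proportions and correlations**: `proportion_table()` (cell type, region
  or region.lineage over confident cells; the region.lineage category
  crosses predicted region with a user-supplied cell-type → lineage map,
  since no canonical definition exists), `correlate_proportions()` (Pearson
  over the category union with zero fill; pairs with fewer than 3 aligned
  categories carrying variance return NA with a warning — a correlation
  over two points is ±1 by construction and carries no information),
  `compare_score_distributions()` (two-sided Wilcoxon rank-sum, exact for
  small untied samples), and `correlate_score_vs_proportion()` (Spearman).

### Statistical conventions

One-vs-rest markers (`find_markers()`) use a two-sided Wilcoxon rank-sum
test per gene — exact for group sizes ≤ 10 without ties, a vectorized
normal approximation with tie and continuity correction otherwise — with
Benjamini–Hochberg adjustment across genes within each label, and
`log2fc = log2((mean(expm1(ln_in)) + 1) / (mean(expm1(ln_out)) + 1))`.
Markers pass with log2fc > 1.5 and FDR < 0.01 (both strict); reference
building stores the full ranking to depth 50 regardless of thresholds so
that top-n marker sets are always defined.

## 3. The synthetic-data generator

`synthetic_atlas_spec()` defines a generative model whose purpose is to
reproduce the *statistical structure* the mapping framework assumes, with
ground truth attached:

- 2,000 genes with lognormal baseline expression (sd 1 on the log scale);
  per-cell library sizes lognormal around **10,000** counts (sdlog 0.35),
  the depth regime of current droplet chemistry v3 data.
- Disjoint 30-gene programs: one per cell type (natural-log uplift 2.0),
  one per region (uplift 1.0), one per midbrain subregion
  (ventral/dorsal, uplift 1.0), and — because regional identity in tissue
  is partly cell-type-specific — one per (region-specific type, region)
  interaction (uplift 1.0). Without the interaction programs every type's
  regional markers would be the same genes, which contradicts the per-type
  regional DEG structure of real atlases and makes region assignment
  degenerate for abundant populations (see §4).
- Counts are negative binomial with common dispersion 0.3 (variance
  `mu + 0.3 mu^2`), no zero inflation — modern UMI data does not require
  it.
- Whole-brain roster: a midbrain-exclusive `DA N`, `Glu N` in forebrain and
  midbrain only, a hindbrain-exclusive `FSTL4 RELN N`, broadly present
  region-specific `GABA N` and `Radial glia`, and pan-regional `Ser N` and
  `Neuroblast` that carry only 15% of the regional uplift
  (`nonspecific_region_attenuation`) — regional identity for such types is
  weak but not exactly zero, mirroring their near-chance kNN scores.
- The midbrain subatlas (default 4,000 cells) holds fine types with
  ventral/dorsal truth labels and the rare subthalamic-like `hDA.STN` at
  0.8% of cells, sharing 80% of the `hDA` program plus a 6-gene
  distinguishing program at uplift **4.0** (`distinguishing_effect`).
  Discrete-subtype markers such as PITX2 are essentially on/off in real
  data; at the shared-program effect size the distinguishing direction's
  eigenvalue sits below the Marchenko–Pastur noise edge of a 2,000-gene
  PCA and no PC basis could resolve a 0.8% subtype at all — the stronger
  uplift is what makes the emulated subatlas a subatlas in which the rare
  type exists as a resolvable population.
- `generate_mixture()` produces region mixtures at exact ratios
  (largest-remainder rounding), drawing by default from the
  **region-specific** types of each region: benchmark mixtures represent
  cells whose regional identity is transcriptomically defined. `types =
  "all"` includes the pan-regional types, whose regional labels are then
  only weakly recoverable by construction. Optional off-manifold noise
  cells express no program at all. `generate_culture_query()` builds
  arbitrary designed compositions (whole-brain types and/or midbrain fine
  types); `generate_ventral_gradient()` scales the ventral program over
  designed levels.
- Everything is seeded hierarchically (`derive_seed()`): gene baselines
  depend only on the spec seed, so references and queries generated from
  one spec share a manifold; each draw is bit-reproducible.

**What the generator does not emulate:** batch effects and donor structure,
ambient RNA and doublets, realistic gene–gene correlation beyond the
program blocks, marker genes with near-zero baseline (programs ride on
ordinary baselines here), and protocol-specific expression. Tests passing
on these simulations therefore demonstrate the pipeline's logic and
statistics, not robustness to real-data artefacts — the main one being that
anchor-free projection is untested against strong batch effects.

## 4. Behaviour of binned-control scores that shapes the design

Because control genes are matched on *query-wide* mean expression, a
marker set expressed by a large fraction `f` of the query has its controls
drawn from bins already inflated by that expression; the score margin of a
true expresser scales like `(1 − f) × effect`. Three consequences, all
verified in the test suite:

1. **A fully pure query cannot be region-scored.** If every cell expresses
   the regional program, all three region scores collapse toward 0 and the
   argmax is noise. Region assignment needs within-query contrast; real
   cultures (25–35% on-target regional identity for several published
   protocols) provide it naturally, and the package's culture benchmarks
   are therefore heterogeneous (60–75% midbrain plus off-target cells), not
   pure.
2. **Uniform shifts split symmetrically.** Adding +1 to a set in half the
   cells yields scores near +0.5/−0.5, not +1/0 — the contrast, not the
   level, is the invariant quantity.
3. **Confidence filtering of garbage cells needs the predicted type's
   markers to be expressed somewhere in the query.** A noise cell predicted
   as a type absent from the query scores ~0 (coin flip against the strict
   threshold); predicted as a present type it scores robustly negative.
   The filter benchmark therefore uses a query containing every reference
   type.

## 5. Problem sizes and runtime

The validation suite uses the generator's study-scale defaults: a
2,400-cell / 2,000-gene whole-brain reference (150 cells per type-region
block), a 4,000-cell midbrain reference, 6,000-cell mixture queries,
3,000–4,000-cell culture queries, and 1,000 GSEA permutations. The complete
test suite runs in roughly five minutes on one CPU; the acceptance script
in under two. Small-scale unit fixtures (600 genes, 40 cells per block)
exercise the same code paths in seconds.

## 6. Known limitations

- Weighted-kNN transfer with reference-basis projection does not correct
  batch effects; strongly shifted queries will lose confidence rather than
  be rescued.
- Preranked GSEA against co-regulated marker sets is anti-conservative
  under label permutations (inter-gene correlation inflates |ES| relative
  to a gene-permutation null); `identity_strength()` p-values should be
  read as descriptive, and comparisons between genuine and shuffled
  assignments done on NES, as in the tests.
- The region vocabulary is fixed to forebrain/midbrain/hindbrain; the
  region.lineage category depends on a user-supplied lineage map.
- The 0.65 specificity criterion and the 1,000-cell gate are conventions
  adopted from the framework's field use, exposed as parameters rather than
  re-derived.
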