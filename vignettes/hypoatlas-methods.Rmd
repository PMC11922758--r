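---
title: "Methods: consensus cell-type trees, cross-species matching, spatial assignment and effector genes"
author: "hypoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus cell-type trees, cross-species matching, spatial assignment and effector genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hypoatlas implements the computational core of a single-nucleus
cell-type atlas pipeline: quality control, multi-level consensus
clustering with marker-based tree pruning, cross-species cluster
matching, spatial region assignment from deconvolution abundances, and
GWAS effector-gene prioritization. Every stage can be exercised on
synthetic data with planted ground truth, which is how the package
tests itself. This vignette explains the models, the tunable
parameters, and the design choices made where the methods literature
leaves the design open.

## Quality control

Nuclei are kept when they have at least `min_umi` UMIs (default 800),
at most `max_mito` mitochondrial fraction (default 0.10) and are not
flagged as doublets. The bounds are read as inclusive ("minimum of
800" keeps a nucleus with exactly 800 UMIs). After the nucleus-level
filters, whole clusters are removed when **more than**
`doublet_cluster_fraction` (default 0.75, strict) of their members are
doublet-flagged — doublet-dominated clusters are artefacts even for
their singlet members. Per-sample threshold overrides are accepted as
an explicit table; only the global defaults are built in because
sample-specific cutoffs are a property of each dataset.

## Leiden ensembles and hybrid bipartite graph consensus

A single graph-clustering run is noisy near cluster boundaries, so the
pipeline clusters an embedding many times and condenses the runs. A
shared kNN graph (Euclidean metric, undirected union of neighbour
sets, `k_neighbors = 15` by default) is built once per embedding;
Leiden community detection (modularity objective) runs `n_runs` times
per resolution with seeds `base_seed + 0..n_runs-1`. The reference
analysis used 100 runs; the package default is 20, which is where the
ensemble's consensus stops changing on the synthetic benchmarks and
keeps the test suite fast.

Consensus uses the hybrid bipartite graph formulation: cells and
(run, cluster) pairs are the two vertex sets of a bipartite graph with
an edge where a cell belongs to that run-cluster. The
degree-normalized adjacency is embedded by its top-`k` left singular
vectors (the spectral variant of the formulation), rows are normalized
and k-means clusters the cell vertices. `k` defaults to the median
per-run cluster count — the number of clusters the ensemble itself
considers typical. Two numerical choices matter:

* k-means is seeded deterministically from the problem dimensions, so
  `consensus_partition` is a pure function of its inputs;
* the spectral solution is polished by a greedy single-cell pass that
  locally maximizes the *co-association agreement* (the mean over cell
  pairs of the ensemble's pairwise vote for the chosen
  together/apart decision), started from the spectral solution and
  from up to a dozen deduplicated run labelings, keeping the best.
  The objective is what the package's oracle tests pin down; the
  multi-start polish is solver machinery. The polish is skipped above
  5,000 cells where the dense co-association matrix becomes the
  bottleneck; at that scale the spectral solution alone is already
  stable because boundary cells are a vanishing fraction.

## Tree reconciliation

Flat consensus partitions at several resolutions are reconciled into a
strictly nested tree: each fine cluster attaches to the coarse cluster
holding the plurality of its cells (ties to the lexicographically
smallest coarse label), then every cell's coarser labels are rewritten
along its cluster's majority path. One fine-to-coarse sweep makes each
coarser level a function of the level below it, so the result is
nested by construction; sweeps repeat to a fixed point (bounded at 50)
and the number of rewritten labels is reported as the reconciliation
cost. A labeling that is already nested has cost 0 and passes through
unchanged.

## Batch-stratified marker test

Markers are found with a van Elteren-style stratified Wilcoxon
rank-sum test: within every batch, the rank-sum of the target cells is
centred at its null expectation; stratum contributions are combined
with weights `1/(n1 + n2 + 1)` and standardized by the tie-corrected
variance, giving a two-sided normal p value. Multiplicative batch
effects shift every cell in a stratum equally and cancel exactly;
strata missing either group are dropped (erroring only if none
remain). P values are Bonferroni-corrected over the genes tested. The
reported effect sizes are the log2 fold change of means with a
pseudocount of 1 and the detection-rate difference.

Under a two-batch null with batch effects the raw p values are
calibrated (the test suite checks a false-positive rate of 0.05 ± 0.01
at 10,000 genes), and on small cases the analytic p agrees with a
stratified permutation oracle to within Monte-Carlo error plus the
normal-approximation error at n = 60 per stratum (~0.01).

## Tree pruning

A tree node must justify its existence against its siblings. Per
pruning iteration, every node with at least one sibling is checked
against three criteria: at least `min_strong_markers` strong sibling
markers (default 5; "strong" = Bonferroni-adjusted p below 0.05 *and*
log2 fold change at least 0.5 versus the pooled siblings — the
significance gate alone would pass trivial effects at large n),
at least `min_cells` cells (default 50), and at most
`max_single_donor_fraction` of cells from one donor (default 0.90,
strict). Failing nodes merge into the sibling with the smallest
Euclidean centroid distance in the embedding, smallest nodes first
(ties by node id, for determinism); a node's children reattach to the
absorbing sibling, so nestedness is preserved. Centroids are kept
current as merges apply within an iteration; markers and criteria are
re-evaluated at each iteration start. The default of 5 iterations
matches the reference analysis; pruning also stops early at a fixed
point. The merge log (node, reason, target, distance) is attached to
the result — the test suite replays it against a brute-force
nearest-sibling computation.

Because "strong marker" is not pinned down in the methods literature,
both the significance level and the fold-change floor are configurable,
and the sibling comparison (rather than versus-all) is used for the
strong-marker count since sibling contrast is what a merge would erase.

## Cross-species matching

Cluster matching between two species consumes any joint embedding.
Steps: (1) homology tables are reduced to a 1:1 gene map by keeping,
for every gene in multiple pairs, only its highest-similarity pair
(ties to the lexicographically smaller partner); (2) per species,
genes are ranked by the number of samples/batches flagging them as
highly variable, top 2,500 per species, intersected (boundary ties are
broken by mean per-sample variance rank); (3) cluster centroids in
the joint embedding are correlated (Pearson, across dimensions);
(4) correlations are *adjusted*: for entry r with row maximum M_i and
column maximum M_j the one-sided adjustments are `2r − M_i` and
`2r − M_j` — a value is penalized by its gap to the best value
involving either cluster — and the returned adjustment is their
minimum, which makes the downstream gate symmetric in both species
(one-sided variants are available behind a flag, since the original
prose is ambiguous about the combination); (5) edges with adjusted
correlation strictly above 0.7 form a bipartite graph; (6) the graph
is pruned to stars: processing nodes in lexical (species, id) order,
any node whose neighbourhood contains a multi-edge node keeps only its
maximum-adjusted edge, iterated to a fixed point (the single pass
described in the original rule does not guarantee the star property on
all topologies, so iteration is the default and single-pass a config
option). Surviving components are typed 1:1, 1:N or M:1.

## Spatial region assignment

Regions are defined by Leiden clustering of spots on their
cluster-abundance vectors (per-cluster z-scored first, so ubiquitous
high-abundance clusters do not dominate the metric; raw scale is a
flag). Merging several spot clusters into one anatomical region is a
curation hook driven by an explicit map.

For cluster c and region r, with `mean_cr` the mean spot abundance:
`adj_cr = mean_cr − median_r'(mean_cr')` centres each cluster's
profile at its across-region median (a ubiquitous cluster gets adj ≈ 0
everywhere); `mad_cr` is the unscaled median absolute deviation of the
spot-level abundances of c within r (no 1.4826 consistency factor —
the plain definition); and `mad_x = adj / mad` measures how many
robust noise units the region's signal rises above the cluster's
typical level. The candidate region is the argmax of adj; it is
assigned iff its mad_x strictly exceeds 10, else the cluster stays
unassigned (NA). The MAD is floored at 1e-6 times the global mean
abundance so zero-variance regions cannot produce infinities; floored
rows are flagged. Manual overrides are applied last and logged, never
silently. Because mad_x is a ratio of two quantities linear in the
abundance scale, assignments are invariant to rescaling the abundance
matrix. Parent-level assignments propagate unchanged to child clusters
of the tree.

The "median regional abundance" is read as the median across regions
of the cluster's regional means — a per-cluster centring — and the MAD
as the spot-level MAD within the region, which the phrase "for each
cluster in each spatial region" supports.

## GWAS effector genes

Cell-type specificity matrices are aggregated by bootstrap: ten random
subsets of 100,000 cells by default, a pluggable specificity function
applied to each, and the elementwise mean taken (genes or cell types
absent from a subset contribute zero, with a warning). Subsets are
drawn independently across replicates; a disjoint-partition mode is a
flag, since "sampling randomly into ten smaller datasets" admits both
readings. The built-in specificity function is deliberately simple —
per gene, the cell-type mean divided by the sum of cell-type means —
because the bespoke content here is the aggregation and the selection
rule, not the specificity score; any gene-by-cell-type scorer with
values in [0, 1] can be plugged in.

Effector genes must clear both gates: specificity strictly above the
95th percentile of the cell type's nonzero specificity values (per
cell type, linear interpolation; a global-pool mode is a flag) in at
least one cell type, and association rank within the top 1,000.
Cell-type prioritization and effector burden both use strict
Bonferroni gates (p < 0.05/452-style), so a p value exactly at the
threshold is not significant.

## The synthetic-data generators

The generators exist so every downstream decision has machine-readable
planted truth.

**Hierarchy.** Cluster centroids are nested: the children of each node
sit at the vertices of a regular simplex with side
`separation × level_decay^(level−1)`, independently randomly rotated
and centred on the parent. Simplex placement makes sibling centroid
distances *exactly* the planted value — with Gaussian random offsets
the realized distances would vary by ~20%, so "the planted separation"
would not actually be planted. The spacing decay (default 0.7) is the
one genuinely constrained choice: classes must be farther apart than
the subtypes inside them, because a kNN graph on well-separated leaf
blobs is disconnected between blobs and no modularity-style objective
can merge disconnected components — with constant spacing the coarse
level would be unrecoverable by graph clustering *in principle*.
Conversely, sibling leaves need roughly five noise SDs of spacing to
be separable at ARI ≥ 0.95. With separation/noise = 8, decay 0.7
places leaf siblings at 5.6 noise SDs — inside that feasibility band
on both sides. Cells get isotropic Gaussian noise around their leaf
centroid, plus plausible UMI/mito/doublet columns so QC has something
to do; donors and batches are assigned independently of the leaves.

**Counts.** Gamma-Poisson (negative binomial, size 2) on log-normal
gene baselines; each leaf owns `markers_per_leaf` genes whose mean is
multiplied by `marker_fold` (default 10) in that leaf only; batches
multiply every gene by a log-normal factor (sd `batch_effect_sd`) —
exactly the nuisance the stratified test must cancel. Cells that end
up with zero total counts get one count of the highest-baseline gene,
so library sizes are always positive. This emulates the overdispersion
a rank-based test sees; it does not model ambient RNA, dropout
structure, gene–gene correlation or depth gradients, so passing tests
say nothing about those failure modes on real data.

**Species pair.** Shared clusters draw both species' centroids from a
common ancestral centroid with independent symmetric perturbations of
sd s per side, giving matched-centroid correlation `1/(1 + s²)`
(`divergence_for_correlation()` inverts this); private clusters are
independent. The divergence default of 1/3 corresponds to r ≈ 0.9,
the regime in which matching is hard but possible.

**Spatial.** Spot abundance = affinity[cluster, region] + Gaussian
noise, clipped at zero; truth assigns a cluster to its unique argmax
region, NA for flat (or tied) affinity rows. The recovery benchmarks
use peak 10, baseline 1, noise sd 0.2 — spot noise at 20% of the
baseline abundance unit. Noise relative to the *contrast* has a hard
ceiling for this score: mad_x ≈ contrast/(0.6745·noise_sd), so noise
above ~15% of the contrast makes mad_x > 10 unattainable for any
contrast; real deconvolution outputs that support confident mad_x
assignments are in the low-relative-noise regime the benchmark
emulates. No spatial coordinates are generated — the scored
operations only consume region membership.

**GWAS tables.** Planted effectors get specificity in [0.95, 1] in one
random cell type and a rank within the top 1,000; non-planted genes
holding a top rank get specificity in [0.01, 0.1] everywhere, far
below any 95th-percentile cutoff of the background distribution
(uniform [0.01, 0.6] with 20% exact zeros); the generator verifies
both properties before returning, so selection recovering exactly the
planted set is a property of the construction, not luck.

All generators are pure functions of their spec including the seed.

## Problem sizes in the test suite

The package validates itself at desk scale: hierarchy recovery uses 3×4
leaves at 200 cells per leaf over 10 seeds; consensus oracles use ≤8
cells against exhaustive enumeration (500 random ensembles); pruning
soundness uses 100 randomized 2×3-leaf trees; calibration uses 10,000
genes at 200+200 cells plus 50 permutation-oracle cases at 10,000
permutations; matching recovery uses 20 shared + 5+5 private clusters
over 10 seeds; the star-property check runs 1,000 random bipartite
graphs against an independent brute-force implementation; effector
recovery plants 426 genes among 20,000. These sizes were chosen so the
whole suite gives stable verdicts in minutes on one core.

## Known limitations

* The embedding is an input; nothing here integrates or batch-corrects
  it. Garbage embeddings give garbage trees, consensually.
* The consensus polish step is quadratic in cells and is skipped above
  5,000 cells; beyond that the spectral solution stands alone.
* The stratified test's normal approximation is inaccurate below ~10
  cells per group per stratum; such strata legitimately carry little
  weight, but p values for tiny clusters should be read with care.
* Doublet detection, deconvolution, specificity scoring (beyond the
  built-in normalized mean) and gene-level GWAS statistics are
  upstream tools; the package consumes their outputs.
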