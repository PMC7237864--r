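---
title: "Reconstructing embryos from per-embryo single-cell transcriptomes: methods and design"
author: "embryostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing embryos from per-embryo single-cell transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryostrat)
```

# Scope

`embryostrat` reconstructs the cellular organization of stereotypically
developing embryos — ascidian-style cleavage embryos are the motivating
system — from high-depth single-cell RNA-seq in which every cell is tracked
to the embryo it came from. Given cells × genes count tables with per-cell
embryo and stage annotation, the package

* normalizes sequencing depth in two steps (coarse total-count scaling, then
  a fine pairwise factor on constitutively expressed genes),
* detects asymmetrically inherited maternal transcripts by a rank-gap
  bipartition screen with exact combinatorial match probabilities,
* discovers cell types within each embryo without priors by SCECTION —
  recursive bipartitioning with 2-metaprofile consensus NMF — and matches
  types across embryos,
* reconstructs the cell-type lineage tree across consecutive cleavage
  stages under the cell-count doubling constraint,
* recovers abstract embryonic axes from within-embryo expression variance
  by PCA with a pole-trend rotation, and projects cells, cell types and RNA
  velocity arrows into that space,
* quantifies constant-rate RNA velocity (v = u − γs) per gene and cell,
* computes geometry-linked scores from segmentation-style tables (relative
  apical surface, cadherin contact strength, sister-volume ratios from
  maternal transcript dilution), and
* measures expression variability (within- versus across-embryo CV, marker
  precision, coordinated upregulation) and fits a piecewise-linear temporal
  model of gene induction.

A synthetic-embryo generator with planted ground truth
(`simulateEmbryoSeries()`) makes every one of these algorithms testable
end-to-end without external data.

# Data model

The central container is `EmbryoExperiment`, a `SingleCellExperiment` with
genes as rows and cells as columns, a `unitTag` recording the expression
scale (`raw_counts`, `rpm`, `log2rpm`, `zscore`), and per-cell `embryo`,
`stage` and optional `knownIdentity` column data. All expression transforms
are explicit unit transitions: `coarseNormalize()` takes raw counts to RPM
(10^6 reads per cell), `clipAndLog()` takes RPM to log2 after flooring at
1 RPM (pseudocounts are implemented by clipping, never by addition, so the
transform is idempotent and zeros map to exactly 0), and `zscoreGenes()`
standardizes genes over a stated cell subset with the n−1 variance,
dropping and reporting zero-variance genes.

# Normalization

Coarse normalization multiplies each cell's counts by a single factor to a
common total. The fine step matches the log2 expression of constitutively
expressed genes (minimum > 64 RPM across all cells) to a reference cell:
the per-cell factor is 2^(−offset) where the offset is the median log2
ratio against the reference. The median is robust to a minority of
genuinely differential genes; a least-squares (mean) offset is available
via `method = "lsq"`. Matching is anchored to one reference cell (the cell
with the median constitutive signal) rather than all pairs — equivalent up
to a global scale and O(n) instead of O(n²). Both steps scale each cell by
one count-independent scalar, and the fine step is idempotent to numerical
precision.

# Maternal factor detection

Before zygotic genome activation, expression differences between cells of
an embryo can only arise from selective RNA inheritance. Candidate genes
(maximum > 16 RPM, ≥ 4-fold between cells after clipping) are rank-ordered
per gene and split at the single largest gap between consecutive ranks.
Because the embryo is bilaterally symmetric, a genuine inherited factor
must single out cells *evenly across embryos*: we require each complete
embryo to contribute exactly the same number of high cells, relaxing to ±1
(after rescaling by completeness) only when incomplete embryos are present.
The strict-equality rule for complete embryos matters: allowing a spread of
1 admits singleton splits (one embryo contributes the lone high cell) and
floods the screen with noisy constitutive genes.

Genes are then grouped by their exact high-cell set
(`groupBipartitions()`); the improbability that independent genes pick the
same cells by chance is quantified exactly:
`subsetMatchProbability(n, sizes)` = Σ 1/C(n,k). Binomial coefficients are
computed by an addition-only Pascal triangle on base-10^9 digit vectors, so
they stay exact beyond the 2^53 double range (the exact decimal string is
attached as an attribute).

# SCECTION

Within one embryo, cells are recursively bipartitioned. At each node, genes
with maximum > 4 RPM and a 16-fold range within the subset (after clipping)
are selected; the subset is clipped, log2-transformed and gene-standardized;
and 50 independent 2-metaprofile NMF runs are averaged into a consensus
matrix (the mean co-assignment indicator). The final two clusters are read
out by average-linkage hierarchical clustering of (1 − consensus), and the
consensus score is the mean within-cluster consensus over cell pairs. A
split is accepted only above 75% consensus; recursion also stops when no
gene passes the filter or the subset has fewer than 3 cells (pairs become
leaves). Leaf labels are split-path strings, so the partition provenance is
a tree.

Two numerical choices deserve explanation:

* **Non-negativity.** Gene standardization produces negative values, which
  NMF cannot factorize; each gene is therefore shifted by its minimum over
  the subset — a per-gene, rank-preserving shift. Factorizing clipped-log
  values directly (no z-scoring) is available via `zscore = FALSE`.
* **Update rule.** We use multiplicative updates minimizing the generalized
  Kullback–Leibler divergence, the rule of the metagene consensus-NMF
  framework this procedure descends from, with random uniform
  initialization, at most 500 iterations and a relative loss tolerance of
  10^-6. We originally implemented Euclidean-loss updates and found that,
  fully converged, they reach essentially the same factorization from any
  random start: the run-to-run consensus is then ≈ 1 even on structureless
  data and the consensus threshold never stops the recursion. The KL
  objective has many local optima, which is precisely what makes restart
  consensus informative: on pure noise the score hovers near the 0.75
  threshold, while genuinely separable structure scores 1.0. Even so, the
  consensus gate should be understood as an *ambiguity* detector (competing
  alternative splits depress it strongly) rather than a pure-noise
  detector; the differential-gene condition is the main noise gate.

Degenerate runs (all cells in one metaprofile) are re-initialized with a
fresh seed and counted; after 10× the requested runs the split fails. Cell
and gene order are canonicalized internally, so results are invariant to
input permutations, and the full recursion is deterministic given (input,
seed).

Across embryos of one stage, per-embryo per-type mean log profiles —
restricted to the union of the discriminative genes the partitions were
built from — are gene-wise centered and scaled within each embryo (removing
embryo-specific trends) and clustered by average linkage; the tree is cut
at the modal per-embryo type count, and types found in a single embryo are
merged into their closest type within that embryo. This merging step is
what absorbs occasional spurious within-embryo oversplits (stable singleton
splits driven by spuriously transcribed loci), which the generator
deliberately plants.

# Lineage reconstruction

Per-type mean log profiles are computed per stage, restricted (when a bulk
stage × gene table is available) to zygotically regulated genes — maximum
bulk expression > 1 RPM and ≥ 2-fold change between the earliest reference
stage and the mother stage. This filter excludes maternal transcripts,
whose total abundance is constant across cleavage stages, from lineage
distances; without it the maternal signal drags the germ-line sister types
toward the wrong mothers. Profiles are gene-standardized per stage
(removing stage trends) and mothers and daughters are matched by Euclidean
distance under the doubling constraint: every mother's daughters must total
exactly twice her cells.

The greedy matching is **daughter-centric**: daughters, in order of
increasing minimum distance to any mother, are assigned to the closest
mother with remaining budget. We first implemented the mother-centric
variant (mothers accumulate closest daughters) and found it structurally
wrong for transcriptionally silent lineages: a daughter's newly activated
genes penalize every candidate mother equally, so a silent impostor
daughter can beat the true daughter for a given mother, whereas from the
daughter's side the inherited genes dominate the comparison. With the
daughter-centric rule the planted germ lineage — whose types have
essentially no zygotic expression — passes through every stage correctly.
Distance ties break lexicographically on the type label and are flagged.

`buildLineageTree()` composes edges across stage pairs, validates the
doubling invariant at every node, and exports Newick
(`lineageNewick()`, labels `stage.type.n`).

Individual cells are embedded on local mother→daughter axes
(`embedOnLineage()`): the progression coordinate is the scalar projection of
(cell − mother mean) on the unit mother→daughter direction (optionally
normalized so the daughter mean is at 1); a second coordinate orders cells
of a type along a greedy nearest-neighbor chain.

# Embryonic axes

Within one embryo, genes varying ≥ 4-fold (after clipping) are
log-transformed and decomposed by PCA over cells. The leading pair of
components is rotated by the 2D orthogonal rotation that zeroes the pooled
within-pole covariance — the poles being the two halves of the embryo's
first consensus split. This rotation diagonalizes the pooled within-pole
covariance of the leading coordinate pair; the coordinate carrying the
larger within-pole variance is the *tangential* axis (anterior–posterior in
the motivating system) and becomes axis 1, the other separates the poles
and becomes axis 2. Orientation is fixed deterministically: anchor cells
(e.g. the posterior germ pair) get negative axis-1 coordinates and the
first pole is positive on axis 2. Projections are
(x − x̄)·axis on the space's genes and clipped-log scale; later-stage cells
and type mean profiles can be projected into an earlier stage's space.
`classifierAxis()` builds finer coordinate pairs from the difference of two
type-set mean profiles together with the leading residual principal
direction (orthogonal by construction).

Axis directions recovered independently in different embryos agree up to
sign; `alignAxesAcrossEmbryos()` harmonizes signs and reports pairwise
|cos| together with the closed-form null probability for random unit
vectors in d dimensions (cos² ~ Beta(1/2, (d−1)/2)).

# RNA velocity

Under the constant-rate model, the steady state obeys u ≈ γs; γ is fitted
per gene as the least-squares slope through the origin of unspliced on
spliced counts, restricted to cells in the top decile of spliced expression
(ties included; with fewer than 10 expressing cells, all of them, minimum
3). Velocity v = u − γs and the extrapolated spliced signal u/γ are
computed per cell and gene with no pooling or smoothing of any kind. Genes
with all-zero spliced counts or γ = 0 are flagged. Arrows are drawn by
projecting the clipped-log spliced profile (base) and extrapolated profile
(tip) on the same embedding. Note that γ is only identified when the data
include steady-state cells: fitting within a single mid-induction stage
absorbs the induction excess into γ, which is why velocity analyses here
pool cells from consecutive stages.

# Geometry-linked scores

`relativeApicalSurface()` divides each cell's exterior-facing (apical)
surface by its own total surface — per-cell normalization keeps the
quantity dimensionless and in [0, 1]. The cadherin contact strength of cell
i is Σ_j min(C_i, C_j) · l_ij over apical neighbors j, with expression on
the RPM scale (the score multiplies an expression level by a physical
boundary length). Sister volume ratios follow from mass conservation of a
non-transcribed RNA: v1/v2 = (x0 − x2)/(x1 − x0); the multi-gene form
reports per-gene ratios and their median, and negative ratios (violating
conservation) are flagged.

# Noise and timing

`cvWithinVsAcross()` compares, per gene (maximum > 16 RPM in the embryo),
the CV across an embryo's cells with the mean CV over 100 random samplings
of equally many same-stage cells. `findMarkerGenes()` screens type means
(maximum > 4 RPM, ≥ 4-fold between high and low type groups, the grouping
by the same rank-gap operator used for maternal factors) and reports, per
marker, the fraction of expressing cells and the median level among
expressing cells in marker-positive versus -negative categories.
`coordinationAnalysis()` rescales upregulated genes so the mother-type mean
maps to 0 and the daughter-type mean to 1, sums rescaled levels per embryo
and type, and tests the cross-type correlation against an embryo-label
permutation null (exact enumeration when cheap, otherwise ≥ 1000 draws).

The temporal model posits that gene i is 0 before onset t0_i and rises
linearly at rate α_i, while cell j has latent capture time t_j. The fit
alternates two exact steps: per gene, the onset is scanned over the gaps
between sorted cell times with a closed-form line fit on the active cells;
per cell, the objective is piecewise quadratic in t with breakpoints at the
onsets, and every interval has a closed-form minimum. The exact inner
solves replace generic 1D searches because they are cheap at this problem
size and guarantee monotone descent. The likelihood is invariant under
affine time reparameterization; the gauge is fixed by centering cell times
and scaling so the mean rate is 1. Cells earlier than every onset are
unconstrained (any sufficiently early time fits exactly), so planted-truth
comparisons match rates up to a single scale and times up to an affine map
on the constrained cells.

# The synthetic-embryo generator

`simulateEmbryoSeries()` draws raw counts, a spliced/unspliced pair,
per-cell geometry and a volume-weighted pseudo-bulk table from a fixed
bilaterally symmetric type hierarchy (1 type at the 2-cell stage through 11
at the 64-cell stage; {4,4,4,2,2} at the 16-cell stage), with planted truth
returned as an `EmbryoTruth` object. The generator encodes the study
conditions the package is validated under:

* **Markers.** Each non-carrier type carries 8 zygotic marker genes,
  activated at the type's stage and maintained in descendants; log2
  amplitudes are drawn uniformly in [4, 8] by default (real marker folds
  span orders of magnitude; a scalar can be supplied to plant one exact
  fold). Marker genes are truly silent (0 RPM) outside their lineage,
  except for spurious transcription in 5% of marker-negative cells at
  10-fold lower level.
* **Maternal factors.** 10 classifier transcripts are concentrated in the
  germ-lineage carrier cells; the total transcript mass per embryo is
  constant, so the concentration scales inversely with carrier volume as
  asymmetric divisions shrink the germ cells (sister volume ratio 3 from
  the 16-cell stage). Segregation is strong but not absolute: the immediate
  somatic sister of each germ division retains 10% of the mother's
  concentration, one generation deep. Zygotic transcription (markers,
  gradients, spurious loci) begins at the 8-cell stage.
* **Gradients.** 20 genes follow the planted anterior–posterior position
  and 20 the animal–vegetal pole (log2 amplitude 3), emulating graded
  signaling; positional jitter is shared within bilateral pairs.
* **Noise.** Within-type biological noise SD 0.5 log2 units; constitutive
  and maternal genes 0.15; per-embryo per-gene offsets SD 0.15 (oocyte
  pool variability — invisible to within-embryo analyses, inflating only
  across-embryo comparisons); negative-binomial counting noise with
  dispersion 0.1; per-cell depth factors log-uniform in [0.5, 2] around a
  3×10^6-read library, mirroring the high-depth regime the methods assume.
* **Constitutive genes and budget.** 150 constitutive genes well above the
  64 RPM floor (a scaled-down version of the several hundred such genes a
  real transcriptome provides), plus 20 filler "bulk" genes absorbing the
  remaining per-cell mass so that planted levels are true reads-per-million.
* **Velocity.** Per-gene degradation rates γ in [0.2, 2]; unspliced means
  equal γ × spliced means except for genes captured mid-ramp
  (`markerPhase < 1`), where unspliced expression is doubled.
* **Timing.** Per-embryo timing offsets, uniform in a configurable window,
  shift the ramp phase of own-stage markers, producing coordinated
  inter-embryo variability.

What the generator does *not* emulate: real transcriptome-wide correlation
structure, amplification artifacts, batch effects, doublets, cell-cycle
variation, or genuinely continuous differentiation states. Passing the
planted-truth tests therefore demonstrates algorithmic correctness under
the stated statistical assumptions, not performance on arbitrary real data.

Two dedicated configurations are used in validation. The axis-recovery
fixture plants only the two orthogonal gradients (60 genes each, no
discrete markers or maternal factors) with gradient noise 0.35 and
dispersion 0.02 — the regime in which axis directions are strongly
reproducible across embryos, as the motivating data show. The cell-type
recovery fixture plants the 16-cell structure with one exact log2 fold of
4 and noise SD 0.5, two embryos per run, classified per embryo and merged
across embryos.

# Problem sizes used in validation

The test suite and the acceptance script run the full pipelines at desk
scale: 16-cell embryos (two per run, 20 seeds) for cell-type recovery; one
16→32→64 series (112 cells) per seed for lineage reconstruction; eight
4-cell embryos per seed for maternal detection; 20 genes × 40 cells for the
temporal model; 100 cells for degradation-rate recovery. These sizes were
chosen to match the per-embryo scale of the motivating system — the methods
operate within single embryos of at most 64 cells, so nothing larger is
needed to exercise them.

# Known limitations

* The consensus threshold (0.75) is taken as given; no automatic model
  selection over metaprofile counts is performed (`consensusNMF()` exposes
  fixed-k runs).
* Cross-embryo type matching assumes a modal per-embryo type count; a stage
  sampled by a single embryo degenerates to an identity mapping with a
  warning.
* Allele collapsing (summing reads over polymorphic alleles of one gene)
  requires an externally supplied allele→gene map and is not inferred.
* The temporal model's cell times are unidentified before the first onset;
  only the constrained region is compared to planted truth.
* γ estimation assumes steady-state cells are present among the
  top-decile expressers; single-stage snapshots of uniformly ramping genes
  bias γ upward.
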