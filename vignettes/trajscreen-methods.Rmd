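---
title: "Methods: branching pseudo-time, patient scoring and drug screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branching pseudo-time, patient scoring and drug screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscreen)
```

# The model

`trajscreen` analyzes tumor development as a branching process. Cancer cells
are assumed to lie on a one-dimensional manifold in expression space — a
trunk of early cells that splits at a single branch point into two
deterioration paths, one of which (Path II) reaches the most advanced
clinical stage directly while the other (Path I) lingers. Three quantities
carry the analysis:

* per-cell **pseudo-time**: arc length along a principal graph from an
  early-stage root,
* per-cluster pseudo-time **Tᵢ**: the mean pseudo-time of the cells of
  cluster *i*,
* the per-patient **pseudo-time score** `S = Σᵢ Pᵢ·Tᵢ`, where `Pᵢ` are the
  patient's deconvolved cluster proportions. S is linear in P by
  construction and lies between the smallest and largest Tᵢ of the
  contributing clusters. Higher S means the patient's tumor composition
  sits later on the trajectory; the package's working hypothesis, which the
  synthetic survival model reproduces, is that later means a worse
  prognosis.

# Single-cell pipeline

Patient-level QC removes all cells of patients contributing fewer than
`min_cells` (default 20) cells or whose per-cell total counts fail a
Shapiro–Wilk normality test at `normality_alpha = 0.01`. The normality
screen is a stand-in for a visual check of per-patient count distributions;
very small patients produce unstable summaries, which is the symptom both
rules target.

Normalization scales each cell to a common total (default 10⁴) and applies
`log1p`. Highly variable genes are ranked by the variance of standardized
counts `(x − μ)/√μ` clipped at `√n_cells` — a deterministic
variance-stabilized dispersion with no smoothing step. Scaling z-scores each
gene with clipping at ±10. PCA keeps 20 components by default; component
signs are fixed (largest-magnitude loading positive) so results are
reproducible across platforms. `elbow_select()` reports the dimension where
the variance falls below 5 % of the first component's — advisory only.

Clustering builds an undirected kNN graph (k = 20, Euclidean distance in PC
space) and optimizes modularity (multi-level Louvain) at resolution 0.8,
seeded. The number of clusters is not forced; on the default synthetic
conditions the generator's ten clusters are recovered with ARI ≈ 1.
Resolution behaves as in any modularity method: large diffuse groups split
at high resolution, so macroscopic structure should be asked for with a
coarse resolution.

# Trajectory inference

The principal graph is a minimum spanning tree over centroids in PC space.
Two vertex choices are supported:

* **cluster-anchored** (used when a cluster assignment is passed): one
  vertex per cluster. This is the pipeline default; clusters are the unit
  of lineage membership, and cells inherit their cluster's arm. It makes
  branch assignment robust because the skeleton cannot wander within a
  cluster.
* **micro-cluster**: `granularity` k-means centroids (default 12) polished
  by elastic refinement (each vertex is pulled toward the mean of its
  assigned cells blended with the mean of its tree neighbors, then the tree
  is refit; 10 iterations, blend weight 0.3). The default is deliberately
  coarse: with many centroids the MST starts tracing parallel strands
  through wide regions of the manifold and invents branch points, whereas a
  coarse skeleton averages the lateral noise away.

The root is chosen among the tree's **leaves** as the one whose cells are
most enriched for the earliest observed stage (ties: more cells, then lower
index). Restricting to leaves matters: mid-trunk vertices can tie on
stage enrichment, and a trajectory must start at a terminus. Cells are
projected onto their nearest tree edge (ties resolved toward the edge whose
nearer vertex is earlier) and pseudo-time is the arc length from the root to
the projection.

The branch point is a degree ≥ 3 vertex, but not every such vertex
qualifies: an MST grown on noisy data sprouts twigs. A vertex qualifies if
at least two of its downstream subtrees each hold ≥ 5 % of the cells
(`min_branch_frac`), and among qualifying vertices the one whose
*second-largest* downstream subtree is biggest wins (ties: earliest). The
rationale: a genuine branch splits the remaining cells roughly in half,
while noise strands capture a small minority. The two largest downstream
subtrees become the paths; further arms are merged into the geometrically
nearest kept arm with a warning. `PATH_II` is the arm whose terminal cells
(top pseudo-time quartile of the arm) have the later mean clinical stage —
the direct-deterioration path — with ties broken toward the longer arm. A
linear tree yields all-`PRE`/`PATH_I` labels and a warning.

# Branch-dependent expression

Cells ahead of the branch are duplicated into both lineages; each gene is
fit with natural splines in pseudo-time (df = 3, the smallest basis that
captures non-monotone trends), with and without branch interaction, on
log-normalized values (Gaussian family; a negative-binomial option on counts
exists for heavier-tailed data). The likelihood-ratio statistic uses the
number of *distinct* cells rather than design rows: duplication would
otherwise overstate the sample size and inflate the statistic. The cost is
conservatism — the empirical type-I error at α = 0.01 on null simulations is
well below nominal — which is the right side to err on for a screen whose
downstream threshold is q < 10⁻⁸. Q-values are Benjamini–Hochberg. The
default filter keeps genes with q < 10⁻⁸ expressed in > 20 % of cells.

Retained genes are clustered into two sets by Ward linkage on
row-standardized fitted branch profiles (both branches evaluated on a fixed
50-point pseudo-time grid). Enrichment of each set is a hypergeometric
upper-tail test against any user-supplied GMT collection, BH-adjusted, with
a q-value obtained by rescaling with the estimated null proportion
`pi0 = min(1, mean(p > 0.5)/0.5)`.

# Communication and deconvolution statistics

The receptor–ligand score for an ordered cluster pair is the mean of the
ligand's average expression in the sender and the receptor's average in the
receiver. Significance comes from shuffling cluster labels (default 2000
permutations) with the add-one convention `p = (1 + #{null ≥ obs})/(n+1)`,
so p is never 0 and is bounded below by 1/(n+1). Reported interactions
require p < 0.05 *and* a positive score; the interaction count matrix
aggregates both directions by default (configurable).

Deconvolution solves a non-negative least squares problem per bulk sample
over the signature genes (Lawson–Hanson; a linear ν-SVR option with
negatives zeroed and ν chosen from {0.25, 0.5, 0.75} by reconstruction RMSE
mirrors the kernel-regression flavor of the classical tool). Weights are
renormalized to proportions. Each sample gets a reconstruction Pearson
correlation and a permutation p-value whose null refits the sample with its
signature-gene values permuted; samples failing p < 0.05 or r > 0.3 are
flagged, not silently dropped, and proportions are renormalized to sum to
one in all cases. Noiseless mixtures of full-rank signatures are recovered
to machine precision; at the generator's default noise (SD 0.2 on the log
scale) mean per-sample RMSE is ≈ 0.02.

Survival machinery wraps the standard product-limit estimator and the
log-rank test (hypergeometric variance, simultaneous ties). The score
cutpoint evaluates every admissible threshold (both groups ≥ 10 % of the
cohort) and keeps the one maximizing the log-rank statistic. The reported
p-value at that cut is **selection-biased** — the result object says so —
and no multiplicity correction is applied, matching how maximally selected
statistics are conventionally reported; on null data this procedure rejects
far more often than its nominal level, which the test suite demonstrates
rather than hides.

# Drug screening

Cluster markers require AUROC > 0.8 and one-sided rank-sum p < 0.01
(normal approximation with tie correction), plus a cluster mean above the
overall mean as a surrogate for manual curation. The twelve hub-mining
centralities are implemented with their standard definitions; the
orientation is always "larger = more central" (eccentricity enters as its
reciprocal, closeness as the sum of reciprocal distances so disconnected
graphs stay finite). MCC sums `(|C|−1)!` over maximal cliques of size ≥ 2,
so a triangle-free node's MCC equals its degree. EPC is a seeded Monte
Carlo: each edge survives with probability ½ and the score is the average
fraction of vertices still connected to the node (1000 repetitions by
default). BottleNeck builds one deterministic shortest-path tree per source
(parent = smallest-index neighbor one step closer) and counts the sources
for which the node's subtree exceeds a quarter of the component. Hubs are
the intersection of the per-measure top 50 % with boundary ties included —
inclusion is deterministic and conservative (a constant measure excludes
nobody).

Sensitivity prediction fits, per drug, a ridge regression of the reference
response on standardized shared-gene expression, with the penalty chosen by
generalized cross-validation over the fixed grid 10⁻³…10³ (half-decade
steps), then predicts every cell. Cluster sensitivities are mean per-cell
predictions; paths inherit clusters by majority cell branch. The two
screens apply their conjunctions literally: *blocking* = overall mean
logFC < 0 and Path II mean < Path I mean; *cluster-specific* = overall < 0
and targeted-cluster mean < non-targeted mean.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Cells are uniform on a Y topology (branch at 40 % of a total
pseudo-time of 20 arbitrary units; arms equiprobable). Counts are negative
binomial (`variance = μ + φμ²`, φ = 0.3; Poisson at φ = 0) with log-mean =
baseline (uniform on log[0.2, 3]) + effects:

* **cluster markers**: 20 genes per cluster, effect 2 (natural log) inside
  the cluster — the static heterogeneity;
* **time genes**: 200 genes drifting linearly over the whole topology
  (effect 1.5, half up, half down) — the continuous geometry of the
  trajectory. Without them adjacent clusters would be as distant as any
  pair (marker blocks are exchangeable) and no method could order the
  trunk;
* **branch genes**: 100 genes diverging after the branch (per-arm terminal
  deviation 2, half up-in-II/down-in-I, half converse) — the dynamic
  signal the branch test must find.

Library sizes are log-normal with CV 0.1. Stages I–IV are quartiles of a
clinical progression variable that equals pseudo-time on the trunk and
advances 25 % faster on arm II and 25 % slower on arm I
(`stage_asymmetry = 0.25`): stages remain monotone along every lineage,
stage order follows time, and terminal arm-II cells reach stage IV directly
— the asymmetry that makes Path II identifiable at all.

Bulk samples are Dirichlet(α = 1) mixtures of cluster mean log-expression
profiles plus Gaussian noise (SD 0.2); `α = Inf` gives exactly equal
weights. Survival times are exponential with rate
`h₀·exp(β(S − mean S))`, `h₀ = log 2/500` days, `β = 1`; censoring is
uniform on (0, τ) with τ solved numerically so the expected censored
fraction matches `censor_rate` (0.3), the simplest identifiable scheme. The
drug reference plants one blocking drug (loads −0.5 on ten Path-II-up
branch genes, intercept −0.3), one cluster-specific drug (same on the
terminal arm-II cluster's markers), one exactly-null drug, and random
low-weight fillers, with response noise SD 0.1. The PPI generator plants a
hub attached to 60 % of the nodes inside a 9-clique, with sparse background
edges that avoid hub-neighbor pairs (random triangles through the hub would
otherwise hand bystanders high local density), and tethers stray nodes so
the graph is connected; the receptor–ligand list plants one pair whose
ligand marks one cluster and receptor another.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, spatial structure, dropout beyond what the NB produces, multiple
branch points, and real gene–gene correlation structure. Passing recovery
tests therefore shows the machinery is correct and calibrated under the
stated model, not that real tumors meet these assumptions.

# Numerical choices and degenerate inputs

Seeds control every stochastic step (k-means, Louvain, permutations, EPC,
all generators; generator sub-stages use fixed small offsets of the
configured seed). Ties in edge projection resolve toward the earlier
vertex; boundary ties in hub selection are included; constant genes scale
to zero rather than NaN; all-censored survival gives a flat KM curve; a
constant score vector is an error for the cutpoint search (no valid cut);
an edgeless network yields an empty hub set with a warning; permutation
p-values use the add-one convention throughout. Problem sizes in the test
suite (600 cells, 2000 genes, 10 clusters, 50–200 bulk samples, 100
survival replicates, exhaustive graph enumeration to 7 nodes) were chosen
as the smallest at which the statistical claims are stable.

# Known limitations

The trajectory method assumes exactly one dominant branch point; additional
arms are folded into the two main paths. Pseudo-time units are arc length
in PC space and are not comparable across datasets. The maximally selected
cutpoint p-value is anticonservative by design and should be treated as a
ranking device, not a calibrated test. The Gaussian branch test on
log-normalized values is conservative; the NB option trades speed for
fidelity on raw counts. Deconvolution assumes bulk profiles are linear
mixtures of cluster means on the log scale used by the signature, which is
an approximation to the physical mixing of transcripts.
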