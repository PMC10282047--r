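---
title: "Gromov-Wasserstein cell morphology spaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gromov-Wasserstein cell morphology spaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`morphgw` summarizes the shape of a single cell as a metric-measure
space: `n` points sampled evenly from the cell's skeleton, surface or
outline, together with their pairwise distances `d_i` (Euclidean or
geodesic) and uniform point weights. Two cells are compared with the
squared-loss Gromov-Wasserstein (GW) distance

$$
\mathrm{GW}(d_i, d_j) \;=\; \tfrac12\,
\min_{T \in C}\;\sum_{\alpha\beta\gamma\delta}
\bigl| (d_i)_{\alpha\beta} - (d_j)_{\gamma\delta} \bigr|^2\,
T_{\alpha\gamma}\, T_{\beta\delta},
$$

where $C$ is the set of couplings with the prescribed marginals. The
input to GW is each cell's internal distance matrix, so the comparison
is blind to position, rotation and reflection; with geodesic `d_i` it
is additionally blind to bending at articulation points. The matrix of
pairwise GW distances over a set of cells is the *cell morphology
space* on which all downstream analysis operates: Louvain clustering,
UMAP embedding, medoid and average shapes, Laplacian-score feature
association, and the benchmarking statistics.

We report the square root of the optimal objective as the distance
(the GW$_2$ convention), so that the triangle inequality holds and the
space is a genuine metric up to solver tolerance; the raw objective is
also stored in every `gw_result`.

# Sampling cells into point clouds

**Neuron skeletons (SWC).** `sample_swc_even()` walks the tree from
the soma, accumulating arclength along every root-to-leaf path and
emitting a point whenever the distance from the previously emitted
point on that path reaches a step size; the residual carries across
branch points, so samples sit at geodesic radii $0, s, 2s, \dots$ from
the soma ("radially around the soma"). The step giving exactly `n`
points is found by binary search on $[L/(10n),\,L]$ (total cable
length $L$); the sample count is non-increasing in the step, ties are
resolved to the largest step, and the counting pass uses bit-identical
arithmetic to the emission pass so the search cannot disagree with the
walk. Files whose children precede their parents are rejected by
default, mirroring the strict treatment of unsorted reconstructions;
`resort = TRUE` re-sorts them topologically.

**Meshes.** `sample_mesh_vertices()` keeps `n` vertex indices evenly
spaced over the stored vertex order
(`round(k (V-1)/(n-1))`, endpoints included). Segmentation pipelines
emit vertices roughly ordered by spatial proximity, so this
approximates even surface sampling without computing areas; meshes
with fewer than `n` vertices are rejected rather than padded.

**Masks.** `sample_mask_outline()` traces the closed boundary by Moore
neighbour tracing (fixed start at the top-left boundary pixel,
clockwise orientation, so outputs are platform-independent) and emits
`n` points at equal perimeter arclength.

# Intracellular metrics

The Euclidean matrix is the plain pairwise distance of the sampled
coordinates. The geodesic matrix for skeletons is computed on the
sample-chain graph: each sample is joined to the previously emitted
sample on its path with the arclength between them (equal to the step
for even sampling), and all-pairs shortest paths are taken with
Dijkstra's algorithm from every sample — the result is identical to a
Floyd-Warshall evaluation but cheaper on the sparse chain. Because
cross-branch routes pass through the last sample before the branch
point, the chain metric can exceed the exact skeleton metric by at
most one sampling residual per branch (strictly less than two steps);
the tests characterize this against an exact subdivided-skeleton
oracle. Randomly sampled clouds use the exact tree metric instead.
Mesh geodesics default to shortest paths on the edge graph weighted by
edge length — a deterministic upper-bound approximation of surface
geodesics; an exact or heat-method backend can replace it behind the
same contract, and the icosphere tests bound the edge-graph distortion
(about 10-25% above the great-circle length at subdivision 3).

# The GW solver

The objective is a non-convex quadratic over the transportation
polytope. `gw_distance()` uses conditional gradient (Frank-Wolfe):
the linearized subproblem is an exact optimal-transport LP — solved by
the Hungarian algorithm for uniform equal-size marginals and by a
transportation simplex (north-west-corner start, MODI pivoting) in
general — and the step size comes from exact minimization of the
quadratic along the segment.

Because Frank-Wolfe only reaches a stationary point, the solver runs a
small deterministic set of initializations and keeps the best result:
the product coupling, transport plans aligning point eccentricities
(mean distance to the rest of the cell — the first-lower-bound
heuristic), and, on instances of at most 8 points, a fixed family of
multiplicatively perturbed product couplings (trigonometric patterns
at three amplitudes plus a Halton sequence) followed by a
mirror-descent polish. The small-instance start set is exhaustive
enough that the solver matches brute-force oracles (all permutations
plus $10^4$ refined random couplings) to $10^{-6}$ on the test banks;
on production-size cells (50-100 points, where all cells share one
`n`) the structured starts alone are used. No randomness is involved
anywhere, so results are independent of execution order and worker
count. Reported objectives are upper bounds; no global-optimality
claim is made.

Morphologically similar cells — sibling neurons of the same branchy
class — produce heavily multimodal objectives: matching their arbors
is close to a combinatorial branch-assignment problem, and fast
conditional gradient can overshoot the optimum by tens of percent on
such pairs regardless of the structured starts. Since the GW distance
is only a metric *at the optimum*, these upper bounds need not
satisfy the triangle inequality across a population. For analyses
that require metric-grade distances the solver offers
`search = "thorough"`: a large batch of mirror-descent trajectories
from pseudo-random feasible couplings (drawn under a fixed internal
seed, so the mode remains deterministic and leaves the caller's RNG
untouched), whose best candidates are refined by conditional
gradient. Its cost grows as the fourth power of the point count, so
it is intended for reduced point counts; at 10 points per cell it
reproduces brute-force optima and yields pairwise distances whose
triangle inequality holds to machine precision over all triples of
the test bank.

`gw_entropic()` implements the entropy-regularized variant by
mirror-descent iterations whose inner step is Sinkhorn scaling of the
current linearization. The exact product coupling is a stationary
saddle for highly symmetric inputs, so the initialization applies a
small seeded multiplicative jitter (magnitude $10^{-3}$) before
projection; the reported objective is the *unregularized* value at the
returned feasible coupling, which approaches the `gw_distance()` value
as the regularization shrinks.

# Average shapes

For a cluster, the medoid is the member minimizing the summed GW
distance to the others (ties to the smallest index). Every member's
coupling to the medoid is hardened into a permutation by maximum-weight
bipartite assignment — row-argmax can collide, an assignment cannot —
and its distance matrix is conjugated by that permutation so all
matrices share the medoid's indexing.

Averaging has two modes. `eq2` is the coupling-weighted transport of
distances onto the medoid indexing; for hardened couplings the
two-sided transport with cardinality normalization reduces to the
entrywise mean of the aligned matrices, which we return on the
micrometre scale (the raw soft-transport sum is $1/n^2$ of this; we
expose the calibrated version so averages of identical cells reproduce
the cell exactly). `thresholded` first rescales each matrix into an
unweighted graph distance — divide by the smallest positive entry,
round to integers, clip at 2 (0 self, 1 adjacent in the trace, 2
farther) — and then averages, so the entry for a pair of points is 2
minus the fraction of cells in which they are adjacent.

The average shape itself is the shortest-path tree (Dijkstra, rooted
at the soma sample) of the `k = 3` nearest-neighbour graph of the
averaged matrix, i.e. each point is connected to the three points it
is most often adjacent to across the cluster; edge costs are the
averaged matrix minus 1 (clipped at 0) in thresholded mode — one minus
the averaged adjacency — and the raw averaged distances otherwise. Per
point we report a confidence: the nearest-neighbour clipped distance
summed over the cluster members (lower = that point's local
neighbourhood is consistent across cells), plus a [0, 1]-normalized
copy for display. If the kNN graph is disconnected a tree is built per
component with a warning.

# Feature association

A radius neighbour graph connects cells at GW distance at most
$\varepsilon$ (default: the median of the off-diagonal GW distances).
The Laplacian score of a feature $f$ is
$C = \sum_{ij} (f_i - f_j)^2 A_{ij} / \mathrm{Var}(f)$ with the sum
over ordered pairs and the population variance (divisor $N$ — the
variance convention is declared since the definition leaves it open);
low scores mean the feature varies little between morphological
neighbours. Significance is a one-tailed permutation test (low scores
significant) with the $+1$ finite-sample correction:
$p = (1 + \#\{C^{\mathrm{null}} \le C\})/(n_{\mathrm{perm}} + 1)$.

With covariates, each replicate permutes the feature and all
covariates with one shared permutation; the null scores of the feature
are regressed on the null scores of the covariates by ordinary least
squares with intercept (the regression family is a declared choice),
the residuals form the null distribution, and the observed adjusted
score $\tilde C = C - \beta_0 - \sum_m \beta_m C_{h_m}$ is ranked
against them. Benjamini-Hochberg correction runs across the tested
features only; zero-variance features are reported untested. Defaults
follow the analysis conventions the package targets: 1000
permutations, $\varepsilon$ = median GW distance. Expression tables
are normalized as $\log(1 + 5000\,x/\mathrm{total})$ and genes outside
the $[5\%, 90\%)$ detection band are dropped.

# Evaluation statistics

The group-discrimination score is, per label, the ratio of the median
between-group to the median within-group distance, averaged over
labels — a declared median-ratio reading of the classic statistic,
labelled as such. Classification uses stratified 7-fold cross
validation of a $k = 10$ nearest-neighbour vote on the precomputed
distances, with ties broken by the smaller summed distance and then
label order; repeats differ only in the fold-assignment seed, and both
accuracy and the multiclass (Gorodkin) Matthews correlation are
averaged over repeats. Modality comparison standardizes the log of
the off-diagonal distances per modality and places each cell pair on
the 2-simplex with axes $d_M - d_T$, $d_T - d_E$, $d_E - d_M$ (summing
to zero exactly); pairs with a non-positive distance are skipped and
counted, and a flag marks pairs outside the middle 98% of any axis for
plotting exports.

# Synthetic data

The generators exist so that every claim the tests make is computable
without downloads. `generate_neuron()` grows a rooted tree: branch
lengths are Gaussian (mean 50 um, SD 10 um by default), bifurcation
angles Gaussian around 0.4 rad, and the skeleton is discretized at
roughly 5 um with the segment lengths jittered +/-20% and renormalized
to the drawn branch length — real tracings are irregular, and the
jitter also keeps path radii incommensurate so an exact even sample
count always exists. Two classes differing in bifurcation count (2 vs
8) at 20 cells each and 50 sampled points form the default study for
end-to-end recovery; these sizes keep the full suite within minutes on
one CPU while leaving the classes clearly non-trivially separated.
Feature fixtures plant localized features (community indicator times a
strength, default 3, plus unit Gaussian noise), pure-noise features,
and age-confounded features (uniform age 1-5 days); Gaussian noise is
used throughout as the simplest model supporting the calibration and
power claims being tested.

What the synthetic data does not emulate: real reconstruction
artifacts (broken branches, soma segmentation errors), non-Gaussian
expression noise, batch structure, or class-imbalanced populations.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability under clean planted structure, not performance on any
real dataset.

# Numerical choices and edge cases

* Conditional-gradient convergence: relative objective change below
  $10^{-9}$, at most 1000 iterations per start.
* Couplings are hardened only when every selected entry has positive
  mass; otherwise the cell is named in the error.
* Duplicate sampled points are allowed (zero distances; GW tolerates
  them) and warned about.
* Unsorted SWC files, multi-root files and zero-length edges each
  raise a distinct error class; multi-root files can optionally be
  reduced to their largest component, a behaviour exposed without any
  claim about how reference pipelines treat such files.
* Distance matrices are written with 17 significant digits, making the
  text round trip exact for doubles.
* Degenerate inputs (single-node trees, single-pixel masks, all-zero
  matrices in thresholded averaging, constant features or covariates)
  are rejected with specific error classes rather than silently
  repaired.
* Louvain clustering and UMAP embedding take mandatory seeds; UMAP
  runs single-threaded so repeated calls are bit-identical, and
  `n_neighbors` is clamped to $N - 1$ with a warning on tiny spaces.

# Known limitations

GW values are upper bounds from a non-convex solver; with the default
fast search they can exceed the optimum substantially on pairs of
similar branch-rich cells, and only the thorough search at reduced
point counts certifies metric behaviour. On large point counts
different hardware BLAS orderings could in principle select different
stationary points, though all are deterministic on a given machine. The mesh geodesic is an edge-graph approximation that
overestimates surface distance on coarse meshes. The median-ratio
discrimination score is a stand-in reading of the cited statistic.
The test-scale study sizes (tens of cells, 20-50 points) are chosen
for CI budgets; production analyses would use 100+ points per cell and
the same code paths.
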