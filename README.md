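# morphgw

Cell morphology latent spaces from single-cell reconstructions via the
Gromov–Wasserstein (GW) distance.

## The problem

Quantitative comparison of cell shapes — neuronal arbors traced as SWC
skeletons, cortical cells segmented as triangular meshes, 2D cell
outlines from microscopy masks — is usually done with hand-designed
morphometric features, which are modality-specific and discard much of
the geometry. `morphgw` instead treats each cell as a metric-measure
space: `n` points sampled evenly from the cell together with their
pairwise intracellular distances `d_i` (Euclidean, or geodesic along
the skeleton/surface). Two cells are compared by the squared-loss GW
distance

```
GW(d_i, d_j) = 1/2 · min_{T ∈ C} Σ_{αβγδ} |(d_i)_αβ − (d_j)_γδ|² T_αγ T_βδ
```

over couplings `T` with uniform marginals. The construction needs no
landmark correspondence or pre-alignment, is invariant to rigid
motions, and — with geodesic `d_i` — to bending of the cell. The
matrix of pairwise GW distances over a population is a latent space of
cell morphologies that supports clustering (Louvain), 2D embedding
(UMAP), medoid and average shapes of clusters, statistical association
of per-cell features (genes, electrophysiology, mutations) with
morphology via the Laplacian score with covariate-adjusted permutation
nulls, and benchmarking statistics (median-ratio group discrimination,
cross-validated kNN classification, multiclass Matthews correlation,
modality-discrepancy simplex coordinates).

The GW solver is written in the package: conditional gradient with an
exact transportation-LP oracle (Hungarian for uniform equal-size
marginals, transportation simplex otherwise), exact line search,
deterministic multi-start, and an entropic-regularized variant.
Audience: quantitative cell biologists and methods developers who have
per-cell reconstructions and want a modality-agnostic morphology space
in R.

## Worked example

Two synthetic neuron classes (2 vs 8 dendritic branches, 20 cells
each), sampled at 50 points under the geodesic metric, clustered and
classified from the GW space:

```r
library(morphgw)

cells <- list(); labels <- character()
for (cl in c("a", "b")) {
  spec <- neuron_spec(n_branches = if (cl == "a") 2 else 8)
  for (i in 1:20) {
    tree  <- generate_neuron(spec, seed = i + 1000 * (cl == "b"))
    cloud <- sample_swc_even(tree, 50)
    d     <- geodesic_matrix_swc(tree, cloud)
    d$cell_id <- sprintf("%s_%02d", cl, i)
    cells[[length(cells) + 1]] <- d
    labels <- c(labels, cl)
  }
}

space <- gw_pairwise(cells)
space
#> <gw_space> 40 cells, median GW distance 66.37

clusters <- cluster_morphology(space, k_graph = 15, seed = 7)
table(clusters, labels)
#>         labels
#> clusters  a  b
#>        1 20  0
#>        2  0 20

knn_cv_classify(space, labels, k = 10, folds = 7, seed = 3)[c("accuracy", "mcc")]
#> $accuracy
#> [1] 1
#> $mcc
#> [1] 1

cts_score(space, labels)$cts
#> [1] 5.921
```

The two planted classes separate perfectly (clustering agrees exactly
with the class labels; held-out classification is error-free), and the
median between-class GW distance is about 6× the within-class median.
Feature association on the same space:

```r
A  <- radius_graph(space)               # eps = median GW distance
ft <- generate_features(as.integer(factor(labels)),
                        n_localized = 5, n_null = 15, strength = 3, seed = 2)
res <- permutation_test(ft$features, A, n_perm = 1000, seed = 4)
head(res[order(res$q), c("feature", "score", "p", "q")], 3)
#>       feature    score           p           q
#> 1 localized_1 445.5980 0.000999001 0.003996004
#> 2 localized_2 665.4711 0.000999001 0.003996004
#> 3 localized_3 587.8938 0.000999001 0.003996004
```

The five planted morphology-localized features are recovered at
q < 0.005; no noise feature reaches q < 0.05.

A thin CLI wraps the same functions (`inst/cli/morphgw`):

```sh
morphgw fixtures --n-cells 20 --branches 4 --seed 1 --out swc/
morphgw gw --dir swc/ --metric geodesic --n-points 100 --out matrix.gw
morphgw cluster --in matrix.gw --seed 7 --out labels.csv
```

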