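# rarecell

Simulation-based design and benchmarking for rare cell-type detection in
single-cell RNA-seq.

## The problem

Before running a scRNA-seq experiment aimed at finding a rare cell
population — say, a subtype making up 2–10% of a tissue — two design
questions need answers: *how many cells must be profiled* for the rare type
to come out as its own cluster, and *which analysis pipeline* (normalization
→ dimensionality reduction → clustering) finds it most reliably. Neither has
an analytic answer, because detectability depends jointly on the rarity of
the type, how strongly its marker genes are upregulated, sequencing depth,
and the clustering algorithm's behavior on small groups.

`rarecell` answers both questions empirically. It simulates labeled count
matrices with controlled rarity and marker strength, runs pluggable
cell-type-identification backends on them, scores each run against the known
labels, and reads the minimum required cell number off the resulting power
table.

## The model

Counts are drawn from a gamma–Poisson (negative binomial) hierarchy, the
standard generative model for scRNA-seq counts:

1. Baseline gene means: `mu_i ~ Gamma(shape, rate)` (defaults 0.6, 0.3).
2. Marker injection: each of the `m` cell types gets `g` disjoint marker
   genes; for marker `i` of type `k`, the type-`k` mean becomes
   `f_ik * mu_i` with `f_ik ~ Gamma(fC, 1)` (mean `fC`), optionally
   truncated below 1 so every marker is genuinely upregulated.
3. Library sizes: `L_j ~ LogNormal(ln 20000, 0.2)`.
4. Counts for cell `j` of type `k`:
   `x_ij ~ Poisson(lambda_ij * b_ij)` with
   `lambda_ij = mu_ik * L_j / sum_i mu_ik` and `b_ij` a unit-mean gamma
   multiplier whose variance is the biological coefficient of variation
   squared (default 0.1). Optional logistic dropout zeroes entries with
   probability decreasing in expression.

Each simulated dataset carries its ground-truth labels. A clustering result
is scored per cell type by mapping every predicted cluster to the type
holding the plurality of its cells, pooling matched clusters, and computing

```
Precision = TP / (TP + FP),  Recall = TP / (TP + FN),
F1 = 2 * Precision * Recall / (Precision + Recall)
```

The headline quantity is the **rare-type F1** — the F1 of the least abundant
type — alongside the unweighted macro F1.

Three backends ship with the package, all consuming a shared embedding
(total-count normalization, log1p, trend-standardized highly-variable-gene
selection, scaling, PCA):

* `kmeans` — Lloyd k-means with restarts, k set to the number of types;
* `snn_louvain` — shared-nearest-neighbor graph (Jaccard weights, pruned)
  with Louvain modularity clustering and a resolution search toward the
  target cluster count, the Seurat-style recipe;
* `mk_spectral` — averaged multi-bandwidth Gaussian kernels with local
  scaling, kNN sparsification, and normalized spectral clustering, a
  SIMLR-style recipe.

Any function `(embedding, m_target, seed) -> cluster_assignment` can be
added with `register_backend()`.

## Worked example

```r
library(rarecell)

params <- simulation_params(
  n_cells     = 1000,
  proportions = c(0.1, 0.2, 0.2, 0.2, 0.3),  # rare type = 10%
  fold_change = 2,                           # weakest marker regime
  seed        = 101)
dataset <- generate_dataset(params)
#> labeled_counts: 10000 genes x 1000 cells, 5 types
#>   type sizes: 100, 200, 200, 200, 300
#>   markers: 50, 50, 50, 50, 50

embedding  <- preprocess(dataset)
assignment <- cluster_snn_louvain(embedding, k_param = 5, m_target = 5,
                                  seed = 101)
evaluate_clustering(dataset$true_labels, assignment)
#>   type clusters n_true precision recall    f1
#> 1    1        1    100     1.000  0.990 0.995
#> 2    2        3    200     1.000  1.000 1.000
#> 3    3        4    200     1.000  0.995 0.997
#> 4    4        5    200     1.000  1.000 1.000
#> 5    5        2    300     0.993  1.000 0.997
#> rare_type_f1: 0.9950   macro_f1: 0.9978
```

The rare 100-cell type was recovered almost perfectly (99 of 100 cells in a
pure cluster): at this rarity and depth, 1000 cells suffice even at
two-fold markers.

Design questions are answered over a factorial grid:

```r
gs <- grid_spec(proportion_sets = list(c(0.1, 0.2, 0.2, 0.2, 0.3)),
                n_cells_levels = c(500L, 1000L), fold_changes = 2,
                backends = c("kmeans", "snn_louvain"),
                replicates = 2L, master_seed = 7L)
pt <- run_grid(gs)
min_cells_for_threshold(pt, threshold = 0.9)
#>       backend rarity fold_change min_cells achieved f1_at_min
#> 1      kmeans    0.1           2       500     TRUE     1.000
#> 2 snn_louvain    0.1           2       500     TRUE     0.964

select_best_pipeline(pt, rarity = 0.1, fold_change = 2, n_cells = 1000)
#>       backend rare_type_f1 macro_f1 n_replicates rank
#> 1      kmeans            1    1.000            2    1
#> 2 snn_louvain            1    0.999            2    2
```

`min_cells_for_threshold` scans the cell-number levels in increasing order
and reports the first whose aggregated rare-type F1 meets the threshold;
"not achieved" is an explicit outcome. The default grid
(`grid_spec()` with no arguments) is the full 3 × 3 × 3 benchmark design:
rarities {0.1, 0.05, 0.02} × {1000, 2000, 3000} cells × fold changes
{2, 4, 8}.

A command-line interface wrapping the same functions is in
`inst/cli/rarecell` (subcommands `simulate`, `cluster`, `evaluate`, `grid`,
`power`, `best`); dataset bundles are plain Matrix Market + TSV files.

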