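# pulptree

Analysis toolkit for branched single-cell differentiation landscapes —
the kind found in continuously growing tissues such as the rodent
incisor, where a progenitor population feeds several mature fates
(odontoblast-like, apical-like, distal-like) through a continuum of
transient states. It is aimed at computational biologists who want the
full analysis arc of such a system as tested, reusable functions
rather than a one-off script pile.

The package implements:

- **Preprocessing** — detected-gene cell filter, read-support gene
  filter, per-cell mean normalization with log10 transform ("fpm"),
  variance–mean adjustment with per-gene overdispersion scores,
  signature scoring (mean or PC1), signature regression, and
  correlation-based admixture cleanup.
- **Principal-tree trajectories** — SimplePPT-style alternating convex
  optimization of the objective

  J(Z, E, R) = Σᵢₖ Rᵢₖ‖xᵢ − z_k‖² + σ Σ Rᵢₖ log Rᵢₖ + λ Σ₍ₖ,ₗ₎∈E ‖z_k − z_l‖²

  over soft assignments R, tree edges E (minimum spanning tree), and
  principal points Z (defaults λ = 2000, σ = 0.03, M = 200 in a
  cosine working space of 20 PCs); pseudotime as root distance along
  the tree to each cell's edge projection; branch extraction with
  sporadic-branch pruning; and PC1 / path-tree single-trajectory
  variants.
- **Gene dynamics** — penalized degree-5 spline fits of expression on
  pseudotime (mgcv), expression magnitude and BH-adjusted association
  tests, fold/fpm filters, Ward-linkage module clustering, heatmap
  ordering by peak pseudotime, and change-point detection of sharp
  transitions.
- **Stability-selected ICA** — fast fixed-point ICA (nc = 20) on
  standardized overdispersed genes, component stability over 100
  subsamplings of 70% of cells matched by gene-weight correlation,
  a gene-shuffled control, and selection of components above the
  control's stability.
- **Fate priming** — 20-marker fate programs from cluster-mean
  differences, per-cell program intensity, activity thresholds,
  pairwise exclusivity statistics, and kNN projection of mitotic
  cells onto the non-mitotic embedding (cosine distance, 20 PCs).
- **Marker modules** — two-platform fold-change + t-test marker
  filters with recorded, re-derivable criteria; cluster-enrichment
  tables (max/median fold + ANOVA); module scoring across clusters;
  similarity of cells to a reference group in a latent space.
- **A ground-truthed generator** of branched negative-binomial count
  data (three arms, mitotic subpopulation, planted independent
  non-Gaussian progenitor components, second platform at 0.2× depth)
  so every stage has a recovery test without any downloads.

## Worked example

```r
library(pulptree)

sim <- simulate_tree_counts(sim_params(seed = 3))      # 1500 genes x 800 cells
counts <- filter_genes(filter_cells(sim$counts, 800), 5, 10)
expr <- normalize_fpm(counts)
mito <- score_signature(expr, sim$truth$mitotic_genes, "mean")
expr <- regress_out_signature(expr, mito)
adj <- variance_adjust(expr)

coords <- prepare_space(adj, "cosine", n_components = 20)
tree <- fit_principal_tree(coords, lambda = 2000, sigma = 0.03, M = 200,
                           seed = derive_seed(3L, "tree"))
tree
#> principal_tree: 200 points, 199 edges, 761 cells; converged=TRUE (9 iter)

br <- extract_branches(tree)
br$n_branches
#> [1] 3
root <- select_root(tree, names(sim$truth$progenitor)[sim$truth$progenitor])
pt <- assign_pseudotime(tree, root)
sapply(sort(unique(sim$truth$cell_branch)), function(b) {
  cells <- names(pt)[sim$truth$cell_branch[names(pt)] == b]
  cor(pt[cells], sim$truth$cell_pseudotime[cells], method = "spearman")
})
#> fate1 fate2 fate3
#>  0.93  0.93  0.89
```

Three major branches are recovered from the simulated landscape
(234/230/297 cells after sporadic-branch pruning) and pseudotime
tracks the generator's truth within every branch (Spearman ρ
0.89–0.93). The `analysis/` directory holds numbered drivers
(`01_simulate.R` … `07_module_scoring.R`) that run the same arc as a
narrative workflow, writing plain-text tables under `results/`.

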