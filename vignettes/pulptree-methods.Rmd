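---
title: "Modeling branched differentiation with pulptree: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling branched differentiation with pulptree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pulptree analyses continuously renewing, branched differentiation
systems of the kind exemplified by the mouse incisor: a progenitor
population feeding several mature fates through a continuum of
transient states. The package covers the full analysis arc — count
preprocessing, principal-tree trajectory inference, spline modeling of
gene dynamics along pseudotime, stability-based selection of
independent components of progenitor heterogeneity, fate-program
priming analysis, and cross-platform marker-module scoring — together
with a ground-truthed synthetic generator used to validate every
stage. This vignette documents the models, the tunable parameters, the
numerical choices, and the design decisions that were genuinely open.

## Preprocessing

Cells with fewer than 800 detected genes are removed (`filter_cells`;
"fewer than" is strict, so a cell at exactly the threshold is kept),
and genes are required to reach a read threshold in a minimum number
of cells (`filter_genes`, defaults 60 reads in 30 cells, both
inclusive — values appropriate for deep plate-based libraries and
meant to be rescaled for shallower platforms). Expression is
normalized per mean expression level in every cell and
log10-transformed (`normalize_fpm`):

$$\mathrm{fpm}_{gj} = \log_{10}\!\left(1 + \frac{c_{gj}}{\bar c_{j}}\right),$$

where $\bar c_j$ is the mean count of cell $j$. The pseudocount of 1
is recorded in the matrix provenance so alternative conventions remain
comparable; the transform is exactly invariant to rescaling a cell's
counts. Note one consequence used by the tests: because the per-cell
mean includes responding genes, strong programs induce small opposite
shifts in all other genes (a compositional effect); oracles computed
from generator truth take fpm of the true means rather than assuming
non-program genes are flat.

`variance_adjust` fits a loess trend of log gene variance on mean
expression (span 0.5 by default; the smoother is a free choice, since
only the trend's systematic part matters) and rescales centered
expression by the trend sd. The per-gene sd of the adjusted values is
the overdispersion score (1 = on trend) used by "most overdispersed
genes" selections, e.g. the score > 0.9 cut ahead of ICA.

Signature scoring (`score_signature`) supports the two conventions
used in practice: the mean fpm of a gene set, and the first principal
component of cells in the set's subspace, sign-oriented to correlate
positively with the mean score (so the direction of "high signature"
is well defined regardless of PCA sign indeterminacy). The mitotic
signature is removed by per-gene least-squares regression on the
score (`regress_out_signature`), with residuals re-centered to the
original gene means so fpm values keep their scale. Removing the
cycle signature before trajectory fitting matters: without it, the
mitotic subpopulation forms its own spurious branch.

`admixture_cleanup` retains cells whose mean Pearson correlation to
their 200 most-correlated peers exceeds 0.2. Whether the original
analysis computed the correlations on all genes or variable genes is
not determinable; we default to the top 3000 overdispersed genes for
tractability, with a full-gene option.

## Principal-tree trajectories

The working space (`prepare_space`) is a PCA reduction (20 components
by default) of variance-adjusted expression; in cosine mode, cell
vectors are first scaled to unit norm so squared Euclidean distance
equals $2(1-\cos)$ — the cosine-based cell–cell distance. Because
truncation shrinks distances by the discarded variance, coordinates
are rescaled so the mean squared pairwise distance matches the full
space. This keeps the tree parameters' meaning tied to the cosine
distance scale (where squared distances range up to 4) rather than to
the number of retained components; at full rank the factor is exactly
1 and the brute-force distance identities hold.

`fit_principal_tree` implements the SimplePPT idea as block-convex
alternating optimization of

$$J(Z, E, R) \;=\; \sum_{i,k} R_{ik}\,\lVert x_i - z_k\rVert^2
\;+\; \sigma \sum_{i,k} R_{ik}\log R_{ik}
\;+\; \lambda \sum_{(k,l)\in E} \lVert z_k - z_l\rVert^2 ,$$

over soft assignments $R$ (closed form: a Gaussian kernel of bandwidth
$\sigma$, row-normalized; rows are max-shifted before exponentiation
so no cell can underflow to an all-zero row), tree structure $E$ (the
minimum spanning tree over current principal points under
squared-distance weights — exactly the minimizer of the $\lambda$
term), and positions $Z$ (a single symmetric positive-definite solve
of $(\mathrm{diag}(R^\top \mathbf 1) + \lambda L)\,Z = R^\top X$ with
$L$ the tree Laplacian). Each block step is exact, so the objective is
non-increasing; it is logged per iteration and asserted in the tests.
Defaults are the mesenchymal settings $\lambda = 2000$, $\sigma =
0.03$, $M = 200$ principal points; convergence is declared at a
relative objective change below $10^{-5}$ (at most 100 iterations),
and initialization is k-means++ seeding on the cells under the run
seed. $M$ and the number of principal points are one and the same
quantity.

Pseudotime (`assign_pseudotime`) is the distance from a chosen root
along the tree to the cell's orthogonal projection onto its nearest
edge segment (linear interpolation of the endpoint node distances);
projecting onto segments rather than snapping to nodes avoids
pseudotime plateaus. The root is an explicit input — biologically, the
progenitor state; `select_root` picks the principal point nearest the
centroid of a user-supplied progenitor cell set, which is robust to
single-cell nodes.

Branches (`extract_branches`) are maximal edge paths between nodes of
degree other than two, with cells labelled by their projection edge.
Sporadic branches are pruned smallest-first and their cells reassigned
to the nearest surviving branch; pruning does not merge the remaining
branches. The default pruning threshold is 15% of the cells: in a
landscape whose major branches each hold a fifth to a third of the
cells, spurious structures — the progenitor noise blob poking out of
the junction, or lobes induced by progenitor heterogeneity — carry
about 3–13% of cells, well below any major branch. For trees expected
to contain genuinely small populations the threshold should be set
explicitly.

`linear_trajectory_pseudotime` covers the two single-trajectory
variants: a path-constrained principal tree (the fit must come out
with all node degrees at most 2), and first-principal-component
pseudotime, sign-anchored so user-designated anchor cells (e.g.
progenitors) sit at low values.

## Gene dynamics along pseudotime

`fit_gene_dynamics` models each gene's fpm as a penalized degree-5
B-spline of pseudotime (`mgcv::gam`, basis `bs = "bs"`, order 5,
second-difference penalty, smoothness by GCV; basis dimension 10).
"Degree five" is read as the spline order of an otherwise penalized
smooth, matching the behaviour of the underlying fitting routine. The
fitted curve is evaluated on a 100-point grid; the expression
magnitude is the curve's max − min (log10 units, so a 100-fold change
is a magnitude of 2), the association p-value is the smooth-term test,
and Benjamini–Hochberg adjustment is applied across genes. Degenerate
cases: constant genes get magnitude 0 and p = 1 without fitting; a
perfect fit of a non-constant trend (no residual variance, so the
smooth-term test is undefined) is treated as maximally significant.

`filter_dynamic_genes` applies strict inequalities on both axes
("more than 100-fold" excludes a magnitude of exactly 2.0), in fold
mode (log10 threshold) or direct fpm mode (e.g. more than 1 fpm).
Modules are formed by Ward-linkage hierarchical clustering
(`ward.D2`) of per-gene standardized fitted curves under Euclidean
distance, cut at nine modules by default. Heatmap ordering is by peak
pseudotime; the secondary "steep rise" key is operationalized as the
earliest grid point where the fitted derivative exceeds the gene's
magnitude divided by the pseudotime range — the original description
of that secondary ordering is ambiguous, and this is our documented
reading. Ties after both keys break by gene id.

The progenitor-to-committed transition (`detect_transition_point`) is
formalized as a single change-point scan over the pseudotime ordering:
the split maximizing $|\bar v_{\text{left}} - \bar v_{\text{right}}|
\sqrt{n_l n_r}/n$, reported as a transition only when a Welch test at
the best split clears $\alpha = 10^{-3}$ (flat profiles return a
no-transition flag). The original analyses identified this point
visually; the scan makes it reproducible.

## Stability-selected independent components

Progenitor heterogeneity is modeled as independent non-Gaussian
components of the standardized expression of overdispersed genes
(`standardize_for_ica`: overdispersion > 0.9, then per-gene zero mean
and unit sd). `run_ica` estimates components with the fast fixed-point
algorithm (`ica::icafast`) with cells as observations, so cell scores
are the independent axes and the mixing matrix carries gene weights.
For speed, whitening is done once in the smaller cell dimension (the
top-`nc` eigenvectors of the cell–cell Gram matrix are exactly the PC
scores a full SVD would produce); the fixed-point search then runs in
the whitened 20-dimensional space. The search is restarted from the
PCA basis and from seeded random rotations, keeping the solution with
the highest total log-cosh negentropy — symmetric FastICA occasionally
splits a strong source across two components from an unlucky start,
and restarts make the reported decomposition reliable. Components are
ordered by gene-weight energy and sign-oriented so the
largest-magnitude gene weight is positive.

The number of meaningful components is decided by subsampling
stability against a shuffled control (`ica_stability_analysis`):
twenty components are estimated on the full matrix and on 100 random
subsamples of 70% of cells, each full component is matched to its best
subsample component by absolute Pearson correlation of gene-weight
vectors (gene weights, not cell scores, because subsamples share genes
but not cells), and stability is the mean best |correlation|. The
control is the same matrix with every gene's values independently
permuted across cells — marginals preserved exactly, covariation
destroyed — shuffled once and reused across the control arm's runs.
Components whose stability exceeds the control maximum are stable
(an "above the 95th control percentile" rule is also provided), and
the final decomposition is re-run at the selected dimensionality.

Two numerical choices deserve note. First, subsample runs use a single
seeded random initialization rather than restart selection: a
component should count as stable only if it is a genuine attractor
that subsamples rediscover from arbitrary starting points, and
canonicalizing the subsample solutions was observed to inflate the
stability of pure-noise components in both arms. Second, the stable
count on matrices with planted sources is intrinsically variable at
the margin: the data's non-source components and the control's
components draw from nearly the same stability distribution, and the
comparison of the two maxima flips extra components in or out by
±0.01–0.02. The analysis therefore reports the modal stable count
over several generator seeds, which concentrates on the planted
number.

## Fate programs and priming

Fate markers (`define_fate_markers`) are the 20 genes with the largest
mean-fpm difference between a fate cluster and the progenitor
clusters; a gene topping several fates is kept by the fate with the
larger difference and replaced in the others by their next-ranked
gene, so programs are disjoint. Program intensity is the mean fpm of
the markers. Activity calls (`call_active_program`) use an invented
but simple rule — progenitor reference mean + 2 sd — because the
original figures draw thresholds without stating them; the rule's
Gaussian null calibration (≈2.3% of reference-like cells called
active) is tested. Multilineage priming is summarized by pairwise 2×2
co-activation tables, Haldane-corrected odds ratios, and an
exclusivity statistic (the fraction of program-active cells active in
exactly one program; 1 means no detectable priming).

Mitotic cells are re-positioned on a 2D embedding of the non-mitotic
landscape as the mean position of their 10 nearest non-mitotic
neighbours under cosine distance in the 20-PC space
(`project_mitotic_cells`); positions are therefore convex
combinations of real cells. The embedding itself is consumed as input
(t-SNE/UMAP computation is out of scope); a PCA fallback is used in
the analysis drivers.

## Cross-platform marker modules

`two_group_markers` selects genes at least $k$-fold overexpressed
("at least" inclusive; "more than" strict — applied consistently
everywhere) with a two-sided Welch t-test below the p cutoff. Fold
changes are computed on linearized expression ($10^{\mathrm{fpm}} -
1$, floored at 0), since fold refers to expression ratios, while the
test runs on fpm values (the scale the original tests most plausibly
used; both are supported). Zero-variance genes are guarded with
machine epsilon and flagged — note the guard caps the t reference at
one degree of freedom, so such genes carry Cauchy-tailed p-values.
Marker sets intersect across datasets (a marker must pass in every
platform), and every set records its criteria so it can be re-derived
exactly — an audited property. `cluster_enrichment_table` keeps genes
whose max/median ratio of per-cluster linearized means reaches the
fold cut under a one-way ANOVA p cutoff ("medium expression" read as
the median across cluster means). `similarity_to_group` is the mean
Pearson correlation of a cell's latent vector with each reference-group
cell's vector; the latent space is pluggable (a 30-component PCA by
default, standing in for any learned latent space).

## The synthetic generator

`simulate_tree_counts` draws cells uniformly along a rooted star tree
(the root is the progenitor state at the centre; three arms by
default) and builds natural-log mean expression as baseline + library
factor + branch-specific ramps + planted sources + mitotic program,
then samples gene-wise negative-binomial counts (overdispersion
gamma-distributed across genes — Poisson noise would understate the
variability the variance adjustment is built for). Defaults: 800
cells, 1500 genes, library factors log-normal (sd 0.3 natural log),
baseline log-means N(0.3, 1.2²) giving ≈4–5k counts and ≈1000
detected genes per cell.

Each fate's program has 90 genes with logistic pseudotime ramps whose
onsets follow a Beta(1,3) distribution scaled to the first 90% of the
branch and whose tip effects average e² ≈ 7-fold. Concentrating
onsets near the root while keeping a tail of later onsets reflects
how the landscape behaves — fate identity emerges as soon as cells
leave the progenitor state, while expression keeps evolving along the
whole branch — and both halves matter for recovery: early divergence
keeps the three arms separable as branches, and the late tail keeps
pseudotime informative out to the branch tips. An "abrupt" ramp
option (narrow widths) is available for modeling sharp transitions.

A 10% mitotic subpopulation expresses a 40-gene cycle program (+1.5
natural log). Five planted independent sources live only in
progenitor cells (pseudotime < 0.3): each is a sparse bimodal cell
loading (values −1/0/+1, a quarter of progenitors active — sparse
enough to be clearly non-Gaussian, with excess kurtosis ≈ 1) times a
sparse 40-gene weight vector (scale 1.2 natural log), added on the
log-mean scale; loadings are redrawn until pairwise |r| < 0.1. The
second platform re-draws counts from the same means at 0.2× depth,
enough to exercise "must pass in both datasets" filters.

`simulate_progenitor_counts` is the progenitor-heterogeneity
configuration: all cells inside the progenitor window, fate ramps and
the mitotic program off, and library depth constant — so the planted
sources are the only multi-gene structure above gene-wise noise,
matching the question the stability-selected ICA is meant to answer
(per-cell normalization removes depth ahead of ICA in any case).

What the generator does not emulate: ambient RNA, doublets, batch
chemistry, zero-inflation beyond the negative binomial, gene–gene
correlation within programs beyond the shared ramp, and realistic
transcriptome size (1500 genes rather than ~20k). Passing recovery
tests therefore demonstrates correctness of the algorithms under the
stated statistical structure, not robustness to every artifact of
real data.

## Problem sizes and reproducibility

The validation analyses run at the generator's default scale (800
cells × 1500 genes; ICA stability at nc = 20 with 100 subsamples per
arm; trees with M = 200 principal points), which we consider
representative for a single dissected compartment. All randomness
flows from one run seed through `derive_seed(seed, stage)`, so every
stage has its own deterministic stream and whole runs reproduce
bitwise; the pipeline writes a manifest (config, stage seeds, file
hashes, package version) alongside its plain-text artifacts.

## Known limitations

- The principal tree's `lambda`/`sigma` are scale-bound; the
  distance-preserving rescale in `prepare_space` makes them robust to
  the choice of `n_components`, but data whose overall scale differs
  from the cosine convention require re-tuning.
- Branch extraction reports topology from a single fit; junction
  geometry near a dense isotropic progenitor blob can split a
  three-way junction into nearby junctions, which pruning resolves
  only when the resulting middle segment is small.
- The stable-component count inherits the extreme-value variability
  discussed above; single-seed counts can exceed the planted number
  by a few components and should be read modally.
- Spline p-values at the degenerate no-residual boundary are set by
  convention (0), not by the smooth-term test.
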