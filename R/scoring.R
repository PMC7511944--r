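## linearized expression: invert the fpm transform (10^fpm - pseudocount),
## floored at zero, so fold changes refer to expression ratios
linearize_fpm <- function(x, pseudocount = 1) {
  pmax(10^x - pseudocount, 0)
}

## vectorized Welch t-test across rows of two matrices
row_t_test <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  eps <- .Machine$double.eps
  se2 <- v1 / n1 + v2 / n2
  flagged <- se2 == 0
  se2[flagged] <- eps
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / max(n1 - 1, 1) + (v2 / n2)^2 / max(n2 - 1, 1) + eps)
  df[!is.finite(df) | df < 1] <- 1
  p <- 2 * pt(-abs(tstat), df)
  list(p = p, t = tstat, mean1 = m1, mean2 = m2, zero_var = flagged)
}

#' Two-group overexpression markers within one dataset
#'
#' Genes at least `fold_min`-fold overexpressed in group 1 versus group
#' 2 (fold computed on linearized expression, `10^fpm - pseudocount`
#' floored at 0; "at least" is inclusive) with a two-sided t-test
#' p value below `p_max` (strict) on the fpm values. Zero-variance genes
#' are guarded with machine epsilon and flagged.
#'
#' @param expr fpm matrix
#' @param groups per-cell factor/character with exactly 2 levels; group
#'   1 (first level) is the overexpressed side
#' @param fold_min fold threshold (default 3)
#' @param p_max p threshold (default 1e-10)
#' @return character vector of passing genes; full per-gene table in
#'   attribute `table`, criteria record in attribute `criteria`
#' @export
two_group_markers <- function(expr, groups, fold_min = 3, p_max = 1e-10) {
  x <- as_dense(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("groups must have exactly 2 levels")
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  if (length(g1) < 3 || length(g2) < 3) stopf("both groups need >= 3 cells")
  tt <- row_t_test(x[, g1, drop = FALSE], x[, g2, drop = FALSE])
  lin <- linearize_fpm(x)
  l1 <- rowMeans(lin[, g1, drop = FALSE])
  l2 <- rowMeans(lin[, g2, drop = FALSE])
  fold <- ifelse(l2 == 0, ifelse(l1 > 0, Inf, 1), l1 / l2)
  pass <- fold >= fold_min & tt$p < p_max & tt$mean1 > tt$mean2
  genes <- rownames(x)[pass]
  tab <- data.frame(gene = rownames(x), fold = fold, p = tt$p,
                    mean1 = tt$mean1, mean2 = tt$mean2,
                    zero_var = tt$zero_var)
  structure(genes, table = tab,
            criteria = list(fold_min = fold_min, p_max = p_max,
                            group1 = levels(groups)[1],
                            group2 = levels(groups)[2],
                            dataset = dataset_tag(expr)))
}

#' Intersect per-dataset marker sets
#'
#' A marker must pass its criteria in all required datasets (e.g. in
#' both the 10x Chromium and Smart-seq2 platforms); the recorded
#' criteria of every input are kept so the set can be re-derived.
#'
#' @param sets list of gene vectors (as from [two_group_markers()])
#' @param name marker-set name
#' @return character vector (class `marker_set`) with `criteria`
#'   attribute
#' @export
intersect_across_datasets <- function(sets, name = "markers") {
  if (!length(sets)) stopf("need >= 1 dataset set")
  genes <- Reduce(intersect, sets)
  structure(genes, name = name,
            criteria = lapply(sets, attr, "criteria"),
            class = "marker_set")
}

#' Cluster-enriched gene table
#'
#' Keeps genes whose maximum-to-median ratio of per-cluster mean
#' (linearized) expression is at least `fold_min` and whose one-way
#' ANOVA p value across clusters (on fpm) is below `p_max`; each kept
#' gene is assigned to its argmax cluster.
#'
#' @param expr fpm matrix
#' @param cluster_labels per-cell labels
#' @param fold_min max/median ratio threshold (default 4)
#' @param p_max ANOVA p threshold (default 1e-50)
#' @return data.frame (gene, cluster, ratio, p) of enriched genes, with
#'   cluster means in attribute `cluster_means`
#' @export
cluster_enrichment_table <- function(expr, cluster_labels, fold_min = 4,
                                     p_max = 1e-50) {
  x <- as_dense(expr)
  cl <- as.factor(cluster_labels)
  if (nlevels(cl) < 2) stopf("need >= 2 clusters")
  lin <- linearize_fpm(x)
  means <- vapply(levels(cl), function(l)
    rowMeans(lin[, cl == l, drop = FALSE]), numeric(nrow(x)))
  med <- apply(means, 1, median)
  mx <- apply(means, 1, max)
  ratio <- ifelse(med == 0, ifelse(mx > 0, Inf, 1), mx / med)
  pvals <- apply(x, 1, function(y) {
    if (var(y) == 0) return(1)
    tryCatch(oneway.test(y ~ cl, var.equal = TRUE)$p.value,
             error = function(e) 1)
  })
  pvals[!is.finite(pvals)] <- 1
  keep <- ratio >= fold_min & pvals < p_max
  out <- data.frame(gene = rownames(x)[keep],
                    cluster = levels(cl)[apply(means[keep, , drop = FALSE], 1,
                                               which.max)],
                    ratio = ratio[keep], p = pvals[keep],
                    stringsAsFactors = FALSE)
  attr(out, "cluster_means") <- means
  out
}

#' Score marker modules across clusters
#'
#' For every marker set, computes the per-cell mean fpm over its genes
#' and averages those within each cluster (clusters x marker sets);
#' per-cell sums of marker expression are returned alongside.
#'
#' @param expr fpm matrix
#' @param cluster_labels per-cell labels
#' @param marker_sets named list of gene vectors
#' @return clusters x sets matrix with attribute `per_cell` (cells x
#'   sets per-cell mean) and `per_cell_sum`
#' @export
score_modules <- function(expr, cluster_labels, marker_sets) {
  x <- as_dense(expr)
  cl <- as.factor(cluster_labels)
  per_cell <- vapply(marker_sets, function(genes) {
    genes <- unique(intersect(genes, rownames(x)))
    if (!length(genes)) stopf("marker set has no genes present in the matrix")
    colMeans(x[genes, , drop = FALSE])
  }, numeric(ncol(x)))
  per_sum <- vapply(marker_sets, function(genes) {
    genes <- unique(intersect(genes, rownames(x)))
    colSums(x[genes, , drop = FALSE])
  }, numeric(ncol(x)))
  tab <- matrix(NA_real_, nlevels(cl), length(marker_sets),
                dimnames = list(levels(cl), names(marker_sets)))
  for (j in seq_along(marker_sets))
    tab[, j] <- tapply(per_cell[, j], cl, mean)
  colnames(per_cell) <- colnames(per_sum) <- names(marker_sets)
  structure(tab, per_cell = per_cell, per_cell_sum = per_sum)
}

#' Similarity of cells to a reference group in a latent space
#'
#' For every cell, the mean Pearson correlation between its latent
#' vector and each group cell's latent vector (self-correlations
#' excluded). Cells with constant latent vectors get `NA` and are
#' flagged.
#'
#' @param latent cells x d latent coordinates (e.g. 30-component PCA)
#' @param group logical mask or ids of the reference (dividing) cells
#' @return named per-cell similarity; constant-vector cells in attribute
#'   `undefined`
#' @export
similarity_to_group <- function(latent, group) {
  x <- as.matrix(latent)
  if (is.logical(group)) group <- rownames(x)[group]
  gi <- which(rownames(x) %in% group)
  if (length(gi) < 2) stopf("group needs >= 2 cells")
  sds <- apply(x, 1, sd)
  cc <- suppressWarnings(cor(t(x), t(x[gi, , drop = FALSE])))
  self <- match(rownames(x), rownames(x)[gi])
  for (i in which(!is.na(self))) cc[i, self[i]] <- NA
  sim <- rowMeans(cc, na.rm = TRUE)
  sim[sds == 0] <- NA
  names(sim) <- rownames(x)
  structure(sim, undefined = rownames(x)[sds == 0])
}
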