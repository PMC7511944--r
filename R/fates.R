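#' Define fate-specific marker programs
#'
#' For each fate, genes are ranked by the difference between their mean
#' expression in the fate's cluster(s) and in the progenitor cluster(s),
#' and the top `n_markers` (default 20) become that fate's program. A
#' gene reaching the top list of several fates is kept by the fate with
#' the larger difference; the others take their next-ranked gene, so
#' programs are disjoint.
#'
#' @param expr fpm matrix (genes x cells)
#' @param cluster_labels per-cell cluster labels (named by cell)
#' @param fate_clusters named list: fate name -> cluster label(s)
#' @param progenitor_clusters cluster label(s) of the progenitor pool
#' @param n_markers markers per fate (default 20)
#' @return named list of `fate_program` objects: `fate`, `genes`,
#'   `diffs` (named effect sizes)
#' @export
define_fate_markers <- function(expr, cluster_labels, fate_clusters,
                                progenitor_clusters, n_markers = 20L) {
  x <- as_dense(expr)
  if (is.null(names(cluster_labels))) names(cluster_labels) <- colnames(x)
  cl <- cluster_labels[colnames(x)]
  prog_cells <- which(cl %in% progenitor_clusters)
  if (!length(prog_cells)) stopf("no cells in progenitor clusters")
  if (nrow(x) < n_markers) stopf("fewer genes than n_markers")
  prog_mean <- rowMeans(x[, prog_cells, drop = FALSE])
  diffs <- sapply(fate_clusters, function(cls) {
    cells <- which(cl %in% cls)
    if (!length(cells)) stopf("no cells in fate cluster(s) %s",
                              paste(cls, collapse = ","))
    rowMeans(x[, cells, drop = FALSE]) - prog_mean
  })                                          # genes x fates
  rankings <- apply(diffs, 2, function(d) rownames(x)[order(d, decreasing = TRUE)],
                    simplify = FALSE)
  fates <- names(fate_clusters)
  picked <- setNames(vector("list", length(fates)), fates)
  owner <- character(0)                        # gene -> fate that owns it
  repeat {
    for (f in fates) {
      pool <- setdiff(rankings[[f]], names(owner)[owner != f])
      picked[[f]] <- head(pool, n_markers)
    }
    all_genes <- unlist(picked)
    dup <- unique(all_genes[duplicated(all_genes)])
    if (!length(dup)) break
    for (g in dup) {
      claimants <- fates[vapply(picked, function(p) g %in% p, logical(1))]
      winner <- claimants[which.max(diffs[g, claimants])]
      losers <- setdiff(claimants, winner)
      owner[g] <- winner
    }
  }
  lapply(fates, function(f) {
    structure(list(fate = f, genes = picked[[f]],
                   diffs = diffs[picked[[f]], f]),
              class = "fate_program")
  }) |> setNames(fates)
}

#' Score fate-program intensity per cell
#'
#' Intensity of a fate program in a cell is the arithmetic mean fpm of
#' its marker genes.
#'
#' @param expr fpm matrix
#' @param program `fate_program` (or character vector of marker genes)
#' @return named per-cell intensity
#' @export
score_fate_intensity <- function(expr, program) {
  x <- as_dense(expr)
  genes <- if (inherits(program, "fate_program")) program$genes else program
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stopf("markers missing from matrix: %s", paste(missing, collapse = ", "))
  colMeans(x[genes, , drop = FALSE])
}

#' Call cells with an active expression program
#'
#' Threshold rule: progenitor reference mean + `n_sd` standard
#' deviations (default 2) of the reference intensities; cells strictly
#' above the threshold are active. A zero-sd reference degenerates to
#' the mean with a warning.
#'
#' @param intensity per-cell program intensity
#' @param reference_cells ids (or logical mask) of progenitor reference
#'   cells (>= 20 required)
#' @param n_sd threshold multiplier
#' @return logical per-cell activity with attribute `threshold`
#' @export
call_active_program <- function(intensity, reference_cells, n_sd = 2) {
  ref <- if (is.logical(reference_cells)) intensity[reference_cells]
         else intensity[names(intensity) %in% reference_cells]
  if (length(ref) < 20) stopf("need >= 20 reference cells (got %d)", length(ref))
  s <- sd(ref)
  if (s == 0) {
    warnf("zero variance among reference cells; threshold = reference mean")
    thr <- mean(ref)
  } else thr <- mean(ref) + n_sd * s
  structure(intensity > thr, threshold = thr)
}

#' Multilineage-priming analysis across fate programs
#'
#' Given activity calls for two or more fates on the same cells, builds
#' the pairwise co-activation contingency tables, the exclusivity
#' statistic (fraction of program-active cells active in exactly one
#' fate), and pairwise odds ratios of co-activation (Haldane-corrected).
#'
#' @param active logical matrix cells x fates (or list of logical
#'   vectors)
#' @return list: `exclusivity`, `n_active`, `pairs` (data.frame with
#'   counts and odds ratios), `tables` (named list of 2x2 tables)
#' @export
priming_analysis <- function(active) {
  if (is.list(active) && !is.data.frame(active))
    active <- do.call(cbind, active)
  active <- as.matrix(active)
  if (ncol(active) < 2) stopf("priming analysis needs >= 2 fates")
  n_active_per_cell <- rowSums(active)
  any_active <- n_active_per_cell > 0
  exclusivity <- if (any(any_active))
    mean(n_active_per_cell[any_active] == 1) else NA_real_
  fates <- colnames(active) %||% paste0("fate", seq_len(ncol(active)))
  combs <- utils::combn(seq_len(ncol(active)), 2)
  tables <- list(); rows <- list()
  for (i in seq_len(ncol(combs))) {
    a <- active[, combs[1, i]]; b <- active[, combs[2, i]]
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    key <- paste(fates[combs[, i]], collapse = ":")
    tables[[key]] <- tab
    t2 <- tab + 0.5                             # Haldane correction
    or <- (t2[2, 2] * t2[1, 1]) / (t2[2, 1] * t2[1, 2])
    rows[[key]] <- data.frame(pair = key,
                              both = tab[2, 2], only_a = tab[2, 1],
                              only_b = tab[1, 2], neither = tab[1, 1],
                              odds_ratio = or)
  }
  list(exclusivity = exclusivity,
       n_active = sum(any_active),
       pairs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tables = tables)
}

#' Project mitotic cells onto the non-mitotic embedding
#'
#' Each mitotic cell is re-positioned as the mean 2D embedding position
#' of its `k` nearest non-mitotic cells (default 10), neighbours taken
#' by cosine distance in the dimensionally reduced space (20 PCs in the
#' study).
#'
#' @param coords cells x d reduced coordinates (all cells)
#' @param mitotic logical per cell (or ids)
#' @param embedding non-mitotic cells x 2 embedding positions (rows
#'   named by cell)
#' @param k neighbours (default 10)
#' @return list: `positions` (mitotic cells x 2), `neighbors` (list of
#'   id vectors), `k`
#' @export
project_mitotic_cells <- function(coords, mitotic, embedding, k = 10L) {
  x <- as.matrix(coords)
  if (!is.logical(mitotic)) mitotic <- rownames(x) %in% mitotic
  non <- x[!mitotic, , drop = FALSE]
  mit <- x[mitotic, , drop = FALSE]
  if (k > nrow(non)) stopf("k (%d) exceeds number of non-mitotic cells (%d)",
                           k, nrow(non))
  emb <- as.matrix(embedding)[rownames(non), , drop = FALSE]
  unit <- function(m) {
    nr <- sqrt(rowSums(m^2)); nr[nr == 0] <- 1; m / nr
  }
  sim <- unit(mit) %*% t(unit(non))            # cosine similarity
  neighbors <- vector("list", nrow(mit))
  positions <- matrix(NA_real_, nrow(mit), ncol(emb),
                      dimnames = list(rownames(mit), colnames(emb)))
  for (i in seq_len(nrow(mit))) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    neighbors[[i]] <- rownames(non)[nb]
    positions[i, ] <- colMeans(emb[nb, , drop = FALSE])
  }
  names(neighbors) <- rownames(mit)
  list(positions = positions, neighbors = neighbors, k = k)
}

#' Pair cell-cycle score with fate intensity
#'
#' Builds the per-cell (cell-cycle score, fate intensity) table with
#' activity flags on both axes from [call_active_program()] and reports
#' the co-active subset — cells that are cycling and have the fate
#' program on.
#'
#' @param cc_score per-cell cell-cycle score (pc1 signature)
#' @param fate_intensity per-cell fate-program intensity
#' @param reference_cells progenitor reference for both thresholds
#' @param n_sd threshold multiplier (default 2)
#' @return list: `table` (data.frame cell, cc_score, fate_intensity,
#'   cc_active, fate_active), `co_active` (cell ids), `n_co_active`
#' @export
cellcycle_vs_fate <- function(cc_score, fate_intensity, reference_cells,
                              n_sd = 2) {
  cells <- intersect(names(cc_score), names(fate_intensity))
  cc <- cc_score[cells]; fi <- fate_intensity[cells]
  cc_act <- call_active_program(cc, reference_cells, n_sd)
  fate_act <- call_active_program(fi, reference_cells, n_sd)
  tab <- data.frame(cell = cells, cc_score = as.numeric(cc),
                    fate_intensity = as.numeric(fi),
                    cc_active = as.logical(cc_act),
                    fate_active = as.logical(fate_act))
  co <- cells[cc_act & fate_act]
  list(table = tab, co_active = co, n_co_active = length(co),
       thresholds = c(cc = attr(cc_act, "threshold"),
                      fate = attr(fate_act, "threshold")))
}
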