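#' Build the working space for trajectory fitting
#'
#' PCA-reduces variance-adjusted expression to `n_components` cell
#' coordinates. In `"cosine"` mode each cell vector is first scaled to
#' unit norm, so squared Euclidean distance in the (full-rank) reduced
#' space equals `2 * (1 - cosine similarity)` — the cosine-based
#' cell-cell distance used for tree fitting. Because truncating to
#' `n_components` shrinks distances by the discarded variance, the
#' reduced coordinates are rescaled so the mean squared pairwise
#' distance matches the full space; the bandwidth `sigma` and
#' stringency `lambda` of the tree fit therefore keep the same meaning
#' regardless of how many components are retained (the rescale factor
#' is exactly 1 at full rank).
#'
#' @param expr variance-adjusted matrix (genes x cells)
#' @param mode `"cosine"` (default) or `"euclidean"`
#' @param n_components number of PCs
#' @return cells x n_components coordinate matrix
#' @export
prepare_space <- function(expr, mode = c("cosine", "euclidean"),
                          n_components = 20L) {
  mode <- match.arg(mode)
  x <- t(as_dense(expr))                       # cells x genes
  if (n_components >= min(dim(x)))
    stopf("n_components (%d) must be < min(n_cells, n_genes) = %d",
          n_components, min(dim(x)))
  if (mode == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1
    x <- x / nrm
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  coords <- pc$x
  ## mean squared pairwise distance of centered data = 2 * sum of
  ## variances; rescale so the reduced space reproduces the full one
  full_msd <- sum(pc$sdev^2)
  red_msd <- sum(pc$sdev[seq_len(n_components)]^2)
  coords <- coords * sqrt(full_msd / red_msd)
  rownames(coords) <- colnames(expr)
  attr(coords, "mode") <- mode
  attr(coords, "scale_factor") <- sqrt(full_msd / red_msd)
  coords
}

## squared Euclidean distances between rows of a and rows of b
sq_dist <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d[d < 0] <- 0
  d
}

## k-means++ seeding: spread initial principal points over the data
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- sq_dist(x, x[centers[1], , drop = FALSE])[, 1]
  for (i in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    centers[i] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, sq_dist(x, x[centers[i], , drop = FALSE])[, 1])
  }
  x[centers, , drop = FALSE]
}

mst_edges <- function(Z) {
  K <- nrow(Z)
  if (K == 2) return(cbind(1L, 2L))
  d2 <- sq_dist(Z, Z)
  d2 <- (d2 + t(d2)) / 2               # exact symmetry for igraph
  g <- igraph::graph_from_adjacency_matrix(d2, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g)
  igraph::as_edgelist(mst, names = FALSE)
}

tree_objective <- function(d2, R, Z, edges, lambda, sigma) {
  rlogr <- R * log(R)
  rlogr[R == 0] <- 0
  elen <- sum((Z[edges[, 1], , drop = FALSE] - Z[edges[, 2], , drop = FALSE])^2)
  sum(R * d2) + sigma * sum(rlogr) + lambda * elen
}

#' Fit a principal tree to cell coordinates
#'
#' SimplePPT-style alternating convex optimization over three blocks:
#' (i) soft assignments `R` of cells to principal points by a Gaussian
#' kernel of bandwidth `sigma` (rows normalized to 1); (ii) the tree
#' structure as the minimum spanning tree over the current principal
#' points (squared-distance edge weights); (iii) principal-point
#' positions `Z` solving the regularized least-squares system that
#' balances R-weighted proximity to cells against `lambda`-weighted
#' shrinkage of tree edges. The objective
#' `sum_ik R_ik ||x_i - z_k||^2 + sigma * sum R log R +
#' lambda * sum_edges ||z_k - z_l||^2`
#' is non-increasing across iterations and is logged per iteration.
#'
#' @param coords cells x d matrix from [prepare_space()]
#' @param lambda edge-stringency weight (study value 2000)
#' @param sigma assignment bandwidth (study value 0.03)
#' @param M number of principal points (study value 200)
#' @param max_iter,tol convergence controls (relative objective change)
#' @param seed integer seed (k-means++ initialization)
#' @return object of class `principal_tree`: principal points `Z`
#'   (M x d), `edges` (M-1 x 2), soft assignments `R` (cells x M),
#'   `hard_assignment`, `objective` trace, `converged`, `n_iter`,
#'   `params`
#' @export
fit_principal_tree <- function(coords, lambda = 2000, sigma = 0.03,
                               M = 200L, max_iter = 100L, tol = 1e-5,
                               seed = 1L) {
  if (M < 2) stopf("M must be >= 2")
  if (lambda <= 0 || sigma <= 0) stopf("lambda and sigma must be > 0")
  x <- as.matrix(coords)
  n <- nrow(x)
  if (M > n) stopf("M (%d) exceeds number of cells (%d)", M, n)
  set.seed(seed)
  Z <- kmeanspp_init(x, M)
  edges <- mst_edges(Z)
  obj <- numeric(0)
  converged <- FALSE
  R <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(x, Z)
    ## soft assignment: row-wise softmax of -d2/sigma (max-shifted,
    ## so no row can underflow to all-zero)
    e <- exp(-(d2 - apply(d2, 1, min)) / sigma)
    R <- e / rowSums(e)
    ## tree step: MST over current principal points
    edges <- mst_edges(Z)
    ## position step: (diag(colSums R) + lambda * L) Z = t(R) x
    cs <- colSums(R)
    A <- matrix(0, M, M)
    A[edges] <- 1; A[edges[, 2:1]] <- 1
    L <- diag(rowSums(A)) - A
    Z_new <- solve(diag(cs, M) + lambda * L + diag(1e-10, M), t(R) %*% x)
    Z <- Z_new
    obj <- c(obj, tree_objective(sq_dist(x, Z), {
      d2n <- sq_dist(x, Z)
      en <- exp(-(d2n - apply(d2n, 1, min)) / sigma)
      en / rowSums(en)
    }, Z, edges, lambda, sigma))
    if (it > 1) {
      rel <- abs(obj[it] - obj[it - 1]) / (abs(obj[it - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  d2 <- sq_dist(x, Z)
  e <- exp(-(d2 - apply(d2, 1, min)) / sigma)
  R <- e / rowSums(e)
  edges <- mst_edges(Z)
  hard <- max.col(R, ties.method = "first")
  structure(list(
    Z = Z, edges = edges, R = R,
    hard_assignment = setNames(hard, rownames(x)),
    coords = x,
    objective = obj, converged = converged, n_iter = length(obj),
    params = list(lambda = lambda, sigma = sigma, M = M, seed = seed),
    root = NA_integer_), class = "principal_tree")
}

#' @export
print.principal_tree <- function(x, ...) {
  cat(sprintf("principal_tree: %d points, %d edges, %d cells; converged=%s (%d iter)\n",
              nrow(x$Z), nrow(x$edges), nrow(x$R), x$converged, x$n_iter))
  invisible(x)
}

tree_graph <- function(tree) {
  w <- sqrt(rowSums((tree$Z[tree$edges[, 1], , drop = FALSE] -
                     tree$Z[tree$edges[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(tree$edges, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

## project each cell onto the nearest point over all edge segments of
## the tree; returns edge index and the fraction along the edge (from
## endpoint 1). Vectorized over edges.
project_cells_to_edges <- function(tree) {
  x <- tree$coords
  E <- tree$edges
  n <- nrow(x)
  best <- rep(Inf, n); edge_id <- integer(n); frac <- numeric(n)
  for (ei in seq_len(nrow(E))) {
    a <- tree$Z[E[ei, 1], ]; b <- tree$Z[E[ei, 2], ]
    ab <- b - a
    len2 <- max(sum(ab^2), 1e-12)
    t_ <- pmin(pmax((x %*% ab - sum(a * ab)) / len2, 0), 1)[, 1]
    p <- outer(t_, ab) + rep(a, each = n)
    d <- rowSums((x - p)^2)
    upd <- d < best
    best[upd] <- d[upd]; edge_id[upd] <- ei; frac[upd] <- t_[upd]
  }
  data.frame(edge = edge_id, frac = frac, row.names = rownames(x))
}

#' Assign pseudotime from a root principal point
#'
#' Pseudotime of a cell is the distance from the root along the tree to
#' the cell's projection point on its assigned edge segment (linear
#' interpolation between the two endpoint node distances), so root-
#' adjacent cells get minimal values and values increase along every
#' root-to-leaf path.
#'
#' @param tree `principal_tree`
#' @param root principal-point index to root at
#' @return numeric per-cell pseudotime with attributes `root` and
#'   `node_pt` (per-principal-point distances)
#' @export
assign_pseudotime <- function(tree, root) {
  K <- nrow(tree$Z)
  if (!(root %in% seq_len(K))) stopf("root must be a principal-point index")
  g <- tree_graph(tree)
  node_pt <- as.numeric(igraph::distances(g, v = root))
  proj <- project_cells_to_edges(tree)
  e1 <- tree$edges[proj$edge, 1]; e2 <- tree$edges[proj$edge, 2]
  pt <- (1 - proj$frac) * node_pt[e1] + proj$frac * node_pt[e2]
  names(pt) <- rownames(tree$coords)
  structure(pt, root = root, node_pt = node_pt, projection = proj)
}

#' Pick a root principal point from a cell set or gene signature
#'
#' Returns the principal point nearest (in the working space) to the
#' centroid of the given cells — e.g. cells with top progenitor-
#' signature scores — making the root robust to single-cell nodes.
#'
#' @param tree `principal_tree`
#' @param cells character vector of cell ids taken to be root-like
#' @return principal-point index
#' @export
select_root <- function(tree, cells) {
  sel <- rownames(tree$coords) %in% cells
  if (!any(sel)) stopf("none of the given cells are assigned to the tree")
  centroid <- colMeans(tree$coords[sel, , drop = FALSE])
  which.min(sq_dist(matrix(centroid, 1), tree$Z)[1, ])
}

## decompose tree edges into maximal paths between nodes of degree != 2
branch_paths <- function(edges, K) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = K)
  adj <- lapply(seq_len(K), function(k) integer(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], i); adj[[b]] <- c(adj[[b]], i)
  }
  other <- function(ei, v) setdiff(edges[ei, ], v)
  branch_of_edge <- integer(nrow(edges))
  nb <- 0L
  junctions <- which(deg != 2)
  if (!length(junctions)) junctions <- 1L  # cycle-free => can't happen, guard
  for (j in junctions) {
    for (ei in adj[[j]]) {
      if (branch_of_edge[ei] != 0) next
      nb <- nb + 1L
      v <- j; e <- ei
      repeat {
        branch_of_edge[e] <- nb
        v <- other(e, v)
        if (deg[v] != 2) break
        e_next <- setdiff(adj[[v]], e)
        e <- e_next
        if (branch_of_edge[e] != 0) break
      }
    }
  }
  branch_of_edge
}

#' Extract and prune tree branches
#'
#' Branches are maximal edge paths between nodes of degree other than 2.
#' Cells are labelled by the branch of the edge they project onto.
#' Branches holding fewer than `prune_min_cells` cells are pruned
#' smallest-first and their cells reassigned to the nearest surviving
#' branch (distance to that branch's principal points).
#'
#' @param tree `principal_tree`
#' @param prune_min_cells pruning threshold; default
#'   `max(5, ceiling(0.15 * n_cells))` — a branch holding well under the
#'   share of a major branch (each of three major branches carries about
#'   a fifth to a third of the cells) is sporadic
#' @return list: `cell_branch` (per-cell labels `"branch<i>"`),
#'   `branch_sizes`, `pruned` (labels removed), `n_branches`,
#'   `edge_branch`
#' @export
extract_branches <- function(tree, prune_min_cells = NULL) {
  n <- nrow(tree$coords)
  if (is.null(prune_min_cells) || is.na(prune_min_cells))
    prune_min_cells <- max(5L, ceiling(0.15 * n))
  eb <- branch_paths(tree$edges, nrow(tree$Z))
  proj <- project_cells_to_edges(tree)
  cb <- eb[proj$edge]
  ## prune sporadic branches, reassigning their cells
  pruned <- integer(0)
  repeat {
    sizes <- table(factor(cb, levels = sort(unique(eb))))
    sizes <- sizes[!(as.integer(names(sizes)) %in% pruned)]
    small <- sizes[sizes < prune_min_cells]
    if (!length(small) || length(sizes) <= 1) break
    victim <- as.integer(names(small)[which.min(small)])
    pruned <- c(pruned, victim)
    survivors <- setdiff(unique(eb), pruned)
    if (!length(survivors)) stopf("pruning removed all branches")
    ## nearest surviving branch by distance to its principal points
    moved <- which(cb == victim)
    for (i in moved) {
      best <- Inf; bb <- survivors[1]
      for (b in survivors) {
        nodes <- unique(as.vector(tree$edges[eb == b, ]))
        d <- min(sq_dist(tree$coords[i, , drop = FALSE],
                         tree$Z[nodes, , drop = FALSE]))
        if (d < best) { best <- d; bb <- b }
      }
      cb[i] <- bb
    }
  }
  keep <- sort(unique(cb))
  relabel <- setNames(seq_along(keep), keep)
  labels <- paste0("branch", relabel[as.character(cb)])
  names(labels) <- rownames(tree$coords)
  list(cell_branch = labels,
       branch_sizes = table(labels),
       pruned = paste0("branch", pruned),
       n_branches = length(keep),
       edge_branch = eb)
}

#' Single-trajectory pseudotime (path tree or PC1)
#'
#' `method = "principal_tree_path"` fits a principal tree and requires
#' the result to be a simple path (all node degrees <= 2), rooting it at
#' the path end nearest the anchor cells. `method = "pc1"` uses first-
#' principal-component scores of the cells, sign-oriented so the anchor
#' cells sit at low pseudotime; values are shifted to start at 0.
#'
#' @param coords cells x d coordinates (path mode) or expression-derived
#'   coordinates (pc1 mode uses them directly)
#' @param method `"principal_tree_path"` or `"pc1"`
#' @param anchor_cells character ids of cells that should have low
#'   pseudotime (orientation)
#' @param ... passed to [fit_principal_tree()] (path mode)
#' @return per-cell pseudotime
#' @export
linear_trajectory_pseudotime <- function(coords,
                                         method = c("principal_tree_path", "pc1"),
                                         anchor_cells = NULL, ...) {
  method <- match.arg(method)
  x <- as.matrix(coords)
  if (method == "pc1") {
    if (nrow(x) < 3) stopf("pc1 pseudotime needs >= 3 cells")
    s <- prcomp(x, center = TRUE)$x[, 1]
    if (!is.null(anchor_cells)) {
      a <- names(s) %in% anchor_cells
      if (any(a) && mean(s[a]) > mean(s[!a])) s <- -s
    }
    pt <- s - min(s)
    names(pt) <- rownames(x)
    return(pt)
  }
  tree <- fit_principal_tree(x, ...)
  deg <- tabulate(c(tree$edges[, 1], tree$edges[, 2]), nbins = nrow(tree$Z))
  if (any(deg > 2))
    stopf("fitted tree is not a simple path (max degree %d); use a branched workflow",
          max(deg))
  leaves <- which(deg == 1)
  root <- leaves[1]
  if (!is.null(anchor_cells)) {
    pt0 <- assign_pseudotime(tree, leaves[1])
    a <- names(pt0) %in% anchor_cells
    if (any(a) && mean(pt0[a]) > mean(pt0[!a])) root <- leaves[2]
  }
  assign_pseudotime(tree, root)
}
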