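test_that("cosine working space reproduces cosine distances at full rank", {
  set.seed(2)
  x <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
  coords <- prepare_space(x, "cosine", n_components = 19)
  d2 <- as.matrix(dist(coords))^2
  u <- t(x) / sqrt(colSums(x^2))
  cosd <- 2 * (1 - tcrossprod(u))
  expect_equal(d2, cosd, tolerance = 1e-8, ignore_attr = TRUE)
  ## proportional profiles have cosine distance zero
  x2 <- x; x2[, 2] <- 3 * x2[, 1]
  c2 <- prepare_space(x2, "cosine", 19)
  expect_lt(sum((c2[1, ] - c2[2, ])^2), 1e-16)
  ## euclidean mode at full rank preserves pairwise distances
  ce <- prepare_space(x, "euclidean", 19)
  expect_equal(as.matrix(dist(ce)), as.matrix(dist(t(x))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate and blob inputs produce the expected trees", {
  ## all cells identical: principal points collapse, objective ~ 0
  x <- matrix(1, 40, 3, dimnames = list(paste0("c", 1:40), NULL))
  tr <- fit_principal_tree(x, lambda = 10, sigma = 0.1, M = 4, seed = 1)
  expect_lt(max(dist(tr$Z)), 1e-4)
  expect_lt(tail(tr$objective, 1), 1e-6)

  ## two well-separated blobs, M = 2: one point each, pure assignment
  set.seed(6)
  blob <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
                matrix(rnorm(60, 5, 0.05), 30, 2))
  rownames(blob) <- paste0("c", 1:60)
  tr2 <- fit_principal_tree(blob, lambda = 0.1, sigma = 0.05, M = 2, seed = 2)
  purity <- max(table(tr2$hard_assignment[1:30]))
  expect_equal(unname(purity), 30)
  expect_true(all(tr2$hard_assignment[1:30] != tr2$hard_assignment[31:60]))
})

test_that("tree objective is monotone, assignments normalized, fit reproducible", {
  set.seed(5)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(paste0("c", 1:100), NULL))
  tr <- fit_principal_tree(x, lambda = 1, sigma = 0.05, M = 12, seed = 9)
  expect_true(all(diff(tr$objective) <= 1e-6))
  expect_equal(rowSums(tr$R), rep(1, 100), tolerance = 1e-8, ignore_attr = TRUE)
  tr2 <- fit_principal_tree(x, lambda = 1, sigma = 0.05, M = 12, seed = 9)
  expect_identical(tr$Z, tr2$Z)
  expect_identical(tr$edges, tr2$edges)
})

test_that("tree structure step equals exhaustive minimum spanning tree for small K", {
  ## enumerate all labeled spanning trees on K=4 nodes (16 by Cayley)
  set.seed(31)
  Z <- matrix(rnorm(8), 4, 2)
  d2 <- as.matrix(dist(Z))^2
  all_edges <- t(combn(4, 2))
  best <- Inf
  for (pick in combn(nrow(all_edges), 3, simplify = FALSE)) {
    e <- all_edges[pick, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::components(g)$no == 1 && igraph::vcount(g) == 4) {
      w <- sum(d2[e])
      best <- min(best, w)
    }
  }
  got <- pulptree:::mst_edges(Z)
  expect_equal(sum(d2[got]), best, tolerance = 1e-12)

  ## converged fit on 60 points with M=4: realized edge cost is minimal
  ## over all spanning trees of the final principal points
  x <- matrix(rnorm(120), 60, 2, dimnames = list(paste0("c", 1:60), NULL))
  tr <- fit_principal_tree(x, lambda = 0.5, sigma = 0.05, M = 4, seed = 3)
  d2f <- as.matrix(dist(tr$Z))^2
  beste <- Inf
  for (pick in combn(nrow(all_edges), 3, simplify = FALSE)) {
    e <- all_edges[pick, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::components(g)$no == 1 && igraph::vcount(g) == 4)
      beste <- min(beste, sum(d2f[e]))
  }
  expect_lte(sum(d2f[tr$edges]) - beste, 1e-6)
})

## hand-built path tree: 5 nodes on a line, cells sitting at the nodes
path_tree <- function() {
  Z <- cbind(0:4, 0)
  coords <- cbind(c(0, 1, 2, 3, 4), 0)
  rownames(coords) <- paste0("c", 1:5)
  structure(list(Z = Z, edges = cbind(1:4, 2:5),
                 R = diag(5), hard_assignment = setNames(1:5, rownames(coords)),
                 coords = coords, objective = 0, converged = TRUE, n_iter = 1,
                 params = list(lambda = 1, sigma = 1, M = 5), root = NA),
            class = "principal_tree")
}

test_that("pseudotime is the graph distance from the root to each projection", {
  tr <- path_tree()
  pt <- assign_pseudotime(tr, root = 1)
  expect_equal(unname(pt), 0:4, tolerance = 1e-10, ignore_attr = TRUE)
  ## a cell between nodes projects onto the edge, not a node
  tr2 <- path_tree()
  tr2$coords["c3", ] <- c(2.4, 0)
  pt2 <- assign_pseudotime(tr2, root = 1)
  expect_equal(unname(pt2["c3"]), 2.4, tolerance = 1e-10)
  ## node distances strictly increase along any root-to-leaf path
  node_pt <- attr(pt, "node_pt")
  expect_true(all(diff(node_pt) > 0))
  expect_error(assign_pseudotime(tr, root = 99), "root")
})

## hand-built Y tree with a short twig: nodes 1-2-3 trunk; 3 forks to
## (4,5), (6,7) and twig 8
y_tree <- function(cells_per_arm = c(6, 6, 6), twig_cells = 2) {
  Z <- rbind(c(0, 0), c(1, 0), c(2, 0),
             c(3, 1), c(4, 2),
             c(3, -1), c(4, -2),
             c(2.2, 0.6))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(3, 6), c(6, 7), c(3, 8))
  mk <- function(a, b, n) cbind(seq(a[1], b[1], length.out = n),
                                seq(a[2], b[2], length.out = n))
  coords <- rbind(mk(c(0, 0), c(2, 0), cells_per_arm[1]),
                  mk(c(3, 1), c(4, 2), cells_per_arm[2]),
                  mk(c(3, -1), c(4, -2), cells_per_arm[3]),
                  mk(c(2.2, 0.6), c(2.2, 0.6), twig_cells) +
                    cbind(runif(twig_cells, 0, 0.01), 0))
  rownames(coords) <- paste0("c", seq_len(nrow(coords)))
  d2 <- pulptree:::sq_dist(coords, Z)
  hard <- apply(d2, 1, which.min)
  structure(list(Z = Z, edges = edges, R = NULL,
                 hard_assignment = setNames(hard, rownames(coords)),
                 coords = coords, objective = 0, converged = TRUE, n_iter = 1,
                 params = list(lambda = 1, sigma = 1, M = 8), root = NA),
            class = "principal_tree")
}

test_that("branch extraction prunes twigs without merging surviving arms", {
  tr <- path_tree()
  br <- extract_branches(tr, prune_min_cells = 1)
  expect_equal(br$n_branches, 1L)

  set.seed(12)
  ytr <- y_tree()
  br0 <- extract_branches(ytr, prune_min_cells = 1)
  expect_equal(br0$n_branches, 4L)      # trunk + two arms + twig
  br1 <- extract_branches(ytr, prune_min_cells = 5)
  expect_equal(br1$n_branches, 3L)      # twig pruned; arms not merged
  expect_length(br1$pruned, 1)
  ## twig cells reassigned somewhere among survivors
  expect_equal(sum(br1$branch_sizes), nrow(ytr$coords))
})

test_that("single-trajectory pseudotime recovers a linear ordering", {
  set.seed(14)
  line <- cbind(sort(runif(80)), 0) + matrix(rnorm(160, sd = 0.005), 80, 2)
  rownames(line) <- paste0("c", 1:80)
  pt <- linear_trajectory_pseudotime(line, "principal_tree_path",
                                     anchor_cells = rownames(line)[1:5],
                                     lambda = 0.5, sigma = 0.005, M = 10, seed = 2)
  expect_equal(cor(pt, line[, 1], method = "spearman"), 1, tolerance = 0.02)
  expect_lt(mean(pt[1:5]), mean(pt[76:80]))

  ## pc1 mode: anchored orientation, zero-based
  ptc <- linear_trajectory_pseudotime(line, "pc1",
                                      anchor_cells = rownames(line)[1:5])
  expect_equal(min(ptc), 0)
  expect_gt(cor(ptc, line[, 1], method = "spearman"), 0.99)
  expect_error(linear_trajectory_pseudotime(line[1:2, ], "pc1"), ">= 3")
})

test_that("pc1 pseudotime tracks truth on a single-branch simulation", {
  sim <- simulate_tree_counts(sim_params(n_cells = 250, n_genes = 400,
                                         n_branches = 1, n_fate_genes = 90,
                                         n_source_genes = 10,
                                         mitotic_fraction = 0, seed = 17))
  fpm <- normalize_fpm(sim$counts)
  adj <- variance_adjust(fpm)
  coords <- prepare_space(adj, "cosine", 20)
  anchors <- names(sim$truth$cell_pseudotime)[sim$truth$cell_pseudotime < 0.1]
  pt <- linear_trajectory_pseudotime(coords, "pc1", anchor_cells = anchors)
  rho <- cor(pt, sim$truth$cell_pseudotime[names(pt)], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("root selection points at the progenitor end of the tree", {
  set.seed(18)
  line <- cbind(seq(0, 1, length.out = 60), 0) +
    matrix(rnorm(120, sd = 0.01), 60, 2)
  rownames(line) <- paste0("c", 1:60)
  tr <- fit_principal_tree(line, lambda = 100, sigma = 0.01, M = 8, seed = 4)
  root <- select_root(tr, rownames(line)[1:6])
  pt <- assign_pseudotime(tr, root)
  expect_lt(mean(pt[1:6]), mean(pt[55:60]))
  expect_error(select_root(tr, "no_such_cell"), "none")
})
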