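## shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

## default branched simulation (full size), cached
default_sim <- function(seed = 3L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_tree_counts(sim_params(seed = seed))
  .fixture_env[[key]]
}

## small branched simulation for cheap tests
small_sim <- function(seed = 7L, n_cells = 300L, n_genes = 400L) {
  key <- paste0("small", seed, "_", n_cells, "_", n_genes)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_tree_counts(
      sim_params(n_cells = n_cells, n_genes = n_genes,
                 n_fate_genes = 60L, n_source_genes = 25L, seed = seed))
  .fixture_env[[key]]
}

## preprocessed default sim: fpm + mitotic regression + variance adjust
default_processed <- function(seed = 3L) {
  key <- paste0("proc", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- default_sim(seed)
    counts <- filter_genes(filter_cells(sim$counts, 800), 5, 10)
    expr <- normalize_fpm(counts)
    mito <- score_signature(expr, sim$truth$mitotic_genes, "mean")
    expr <- regress_out_signature(expr, mito)
    adj <- variance_adjust(expr)
    .fixture_env[[key]] <- list(sim = sim, counts = counts, expr = expr,
                                adjusted = adj)
  }
  .fixture_env[[key]]
}

## rank-based AUROC of scores for a binary truth
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## random counts matrix with dimnames
random_counts <- function(n_genes, n_cells, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  m
}
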