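#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with the study's values as
#' defaults: cell filter at 800 detected genes, gene filter at 60 reads in
#' 30 cells, mesenchymal principal-tree parameters (lambda = 2000,
#' sigma = 0.03, M = 200) in cosine space, degree-5 spline dynamics with
#' the >100-fold / adjusted p < 1e-5 gene filter and nine modules, ICA
#' stability with nc = 20 components over 100 subsamplings of 70% of
#' cells against a gene-shuffled control (overdispersion cut 0.9), 20
#' fate markers, 10-neighbour mitotic projection in 20 PCs, and the
#' cross-platform marker filters.
#'
#' @param ... overrides for individual entries
#' @return named list of parameters (class `pulptree_config`)
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic data (sizes only; generator defaults cover the rest)
    sim_n_cells = 800L, sim_n_genes = 1500L,
    # preprocess
    min_genes = 800L, min_reads = 60L, min_cells = 30L,
    fpm_pseudocount = 1, variance_span = 0.5,
    admix_k = 200L, admix_min_cor = 0.2, admix_n_top_genes = 3000L,
    # principal tree
    lambda = 2000, sigma = 0.03, M = 200L,
    distance = "cosine", n_pcs = 20L,
    tree_max_iter = 100L, tree_tol = 1e-5,
    prune_min_cells = NA_integer_,   # NA -> max(5, 1% of cells)
    # gene dynamics
    spline_degree = 5L, dyn_min_fold = 100, dyn_max_p_adj = 1e-5,
    n_modules = 9L, dyn_grid = 100L,
    # ICA stability
    ica_nc = 20L, ica_runs = 100L, ica_fraction = 0.7,
    ica_sd_min = 0.9, ica_rule = "above_control_max",
    # fate priming
    n_markers = 20L, knn_k = 10L, active_n_sd = 2,
    # module scoring
    marker_fold_min = 3, marker_p_max = 1e-10,
    enrich_fold_min = 4, enrich_p_max = 1e-50
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config entries: %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pulptree_config")
}

validate_config <- function(cfg) {
  pos <- c("lambda", "sigma", "ica_fraction", "dyn_min_fold")
  for (p in pos) if (cfg[[p]] <= 0) stopf("config '%s' must be > 0", p)
  if (cfg$ica_fraction >= 1) stopf("ica_fraction must be in (0, 1)")
  if (cfg$M < 2) stopf("M must be >= 2")
  if (cfg$ica_runs < 2) stopf("ica_runs must be >= 2")
  nn <- c("min_genes", "min_reads", "min_cells", "n_markers", "knn_k")
  for (p in nn) if (cfg[[p]] < 0) stopf("config '%s' must be >= 0", p)
  invisible(cfg)
}

#' Derive a per-stage seed from the run seed
#'
#' Deterministic, collision-poor mapping from (seed, stage label) to an
#' integer below 2^31, so each stochastic stage draws from its own stream
#' but the whole run is reproducible from one seed.
#'
#' @param seed integer master seed
#' @param stage character stage label
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
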