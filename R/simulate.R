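#' Simulation parameters for the branched-differentiation generator
#'
#' Defaults describe the landscape the analysis assumes: 800 cells and
#' 1500 genes on a rooted tree whose root (progenitor state) sits at the
#' centre of three arms (odontoblast-like, apical-like, distal-like);
#' library sizes log-normal; gene-wise negative-binomial dispersion drawn
#' from a gamma; 90 branch-specific genes per fate following smooth
#' logistic ramps of pseudotime (onsets concentrated near the root so
#' fate identity emerges with commitment); a 10% mitotic subpopulation expressing a
#' 40-gene cycle program; five planted independent non-Gaussian sources
#' restricted to the progenitor region (pseudotime < 0.3); and a second
#' platform replicate at 0.2x sequencing depth.
#'
#' @param n_cells,n_genes matrix size
#' @param n_branches number of arms from the root (>= 1)
#' @param branch_length pseudotime length of each arm
#' @param progenitor_cut pseudotime below which cells count as progenitors
#' @param base_meanlog,base_sdlog natural-log gene baseline distribution
#' @param lib_sdlog sd of natural-log per-cell library factors
#' @param disp_shape,disp_scale,disp_min gamma parameters (and floor) of the
#'   gene-wise negative-binomial size
#' @param n_fate_genes,fate_effect branch program size and natural-log
#'   effect at the branch tip
#' @param ramp_shape `"smooth"` (logistic ramps, default) or `"abrupt"`
#'   (narrow-width ramps)
#' @param mitotic_fraction,n_mitotic_genes,mitotic_effect mitotic program
#' @param n_planted_sources,n_source_genes,source_effect,source_p_active
#'   planted independent components (progenitor-restricted)
#' @param platform_lib_scale depth rescaling of the replicate platform
#' @param progenitor_only if TRUE all cells are drawn in the progenitor
#'   window of a single trunk (used for progenitor-heterogeneity studies)
#' @param seed integer seed
#' @return named list of parameters
#' @export
sim_params <- function(n_cells = 800L, n_genes = 1500L, n_branches = 3L,
                       branch_length = 1, progenitor_cut = 0.3,
                       base_meanlog = 0.3, base_sdlog = 1.2,
                       lib_sdlog = 0.3,
                       disp_shape = 2, disp_scale = 1.5, disp_min = 0.3,
                       n_fate_genes = 90L, fate_effect = 2,
                       ramp_shape = c("smooth", "abrupt"),
                       mitotic_fraction = 0.1, n_mitotic_genes = 40L,
                       mitotic_effect = 1.5,
                       n_planted_sources = 5L, n_source_genes = 40L,
                       source_effect = 1.2, source_p_active = 0.25,
                       platform_lib_scale = 0.2,
                       progenitor_only = FALSE,
                       seed = 1L) {
  p <- as.list(environment())
  p$ramp_shape <- match.arg(ramp_shape)
  if (p$n_cells < 1 || p$n_genes < 1) stopf("n_cells and n_genes must be >= 1")
  if (p$n_branches < 1) stopf("n_branches must be >= 1")
  stopifnot(p$branch_length > 0, p$mitotic_fraction >= 0,
            p$n_planted_sources >= 0, p$fate_effect >= 0)
  if (p$n_branches * p$n_fate_genes + p$n_mitotic_genes +
      p$n_planted_sources * p$n_source_genes > p$n_genes)
    stopf("fate, mitotic and planted-source programs exceed n_genes")
  p
}

logistic_ramp <- function(t, onset, width, length_out) {
  f <- function(x) 1 / (1 + exp(-(x - onset) / width))
  (f(t) - f(0)) / (f(length_out) - f(0))
}

#' Plant independent non-Gaussian sources into log-mean expression
#'
#' Each source is a sparse bimodal cell loading (values in {-1, 0, +1},
#' zero outside `mask`) times a sparse gene-weight vector, added on the
#' natural-log mean scale. Loadings are redrawn until all pairwise
#' correlations within the mask satisfy |r| < 0.1, so the planted
#' components are mutually uncorrelated by construction.
#'
#' @param log_means genes x cells natural-log mean matrix
#' @param n_sources number of components to plant (0 = identity)
#' @param mask logical per cell; loadings restricted to `TRUE` cells
#' @param n_source_genes genes per source (>= 20 by default conditions)
#' @param effect weight scale (natural-log units)
#' @param p_active fraction of masked cells with non-zero loading
#' @param avoid_genes gene indices that may not carry source weight
#' @param max_tries redraw budget for the decorrelation check
#' @return list with `log_means` (modified), `loadings` (cells x sources),
#'   `weights` (genes x sources)
#' @export
plant_independent_sources <- function(log_means, n_sources, mask,
                                      n_source_genes = 40L, effect = 1,
                                      p_active = 0.4, avoid_genes = integer(),
                                      max_tries = 200L) {
  n_genes <- nrow(log_means); n_cells <- ncol(log_means)
  if (n_sources == 0)
    return(list(log_means = log_means,
                loadings = matrix(0, n_cells, 0),
                weights = matrix(0, n_genes, 0)))
  if (!any(mask)) stopf("source restriction mask selects no cells")
  idx <- which(mask)
  loadings <- matrix(0, n_cells, n_sources)
  draw <- function() {
    l <- numeric(length(idx))
    on <- runif(length(idx)) < p_active
    l[on] <- sample(c(-1, 1), sum(on), replace = TRUE)
    l
  }
  for (s in seq_len(n_sources)) {
    for (try in seq_len(max_tries)) {
      cand <- draw()
      ok <- if (s == 1) TRUE else {
        r <- suppressWarnings(cor(cand, loadings[idx, seq_len(s - 1), drop = FALSE]))
        all(is.finite(r)) && max(abs(r)) < 0.1
      }
      if (isTRUE(ok)) break
      if (try == max_tries) stopf("could not decorrelate planted loadings")
    }
    loadings[idx, s] <- cand
  }
  pool <- setdiff(seq_len(n_genes), avoid_genes)
  if (length(pool) < n_source_genes * n_sources)
    stopf("not enough genes outside avoid set for planted sources")
  weights <- matrix(0, n_genes, n_sources)
  gsel <- matrix(sample(pool, n_source_genes * n_sources), ncol = n_sources)
  for (s in seq_len(n_sources)) {
    weights[gsel[, s], s] <-
      effect * runif(n_source_genes, 0.5, 1.5) *
      sample(c(-1, 1), n_source_genes, replace = TRUE)
  }
  list(log_means = log_means + weights %*% t(loadings),
       loadings = loadings, weights = weights)
}

#' Simulate branched-differentiation counts with ground truth
#'
#' Draws cells uniformly along a rooted star tree (root = progenitor
#' state, `n_branches` arms), builds natural-log mean expression as
#' baseline + library factor + branch-specific logistic pseudotime ramps
#' + planted independent sources (progenitor cells only) + mitotic
#' program (mitotic cells only), and samples gene-wise negative-binomial
#' counts. Everything needed to test recovery downstream is returned in
#' the truth object.
#'
#' @param params list from [sim_params()]
#' @return list with `counts` (genes x cells, `dataset_tag` "platform1")
#'   and `truth` (branch labels, pseudotime, programs, planted sources,
#'   mitotic flags, log-mean matrix, parameters)
#' @export
simulate_tree_counts <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  nG <- p$n_genes; nC <- p$n_cells
  gene_ids <- sprintf("g%04d", seq_len(nG))
  cell_ids <- sprintf("c%04d", seq_len(nC))

  branch <- if (p$n_branches == 1) rep(1L, nC) else
    sample.int(p$n_branches, nC, replace = TRUE)
  pt_max <- if (p$progenitor_only) p$progenitor_cut else p$branch_length
  pt <- runif(nC, 0, pt_max)
  progenitor <- pt < p$progenitor_cut

  base <- rnorm(nG, p$base_meanlog, p$base_sdlog)
  libf <- rnorm(nC, 0, p$lib_sdlog)
  size <- p$disp_min + rgamma(nG, shape = p$disp_shape, scale = p$disp_scale)

  ## branch-specific fate programs: disjoint gene blocks, logistic ramps
  fate_genes <- split(seq_len(p$n_branches * p$n_fate_genes),
                      rep(seq_len(p$n_branches), each = p$n_fate_genes))
  width_rng <- if (p$ramp_shape == "abrupt") c(0.01, 0.03) else c(0.05, 0.15)
  fate_programs <- vector("list", p$n_branches)
  log_mu <- matrix(base, nG, nC) + matrix(libf, nG, nC, byrow = TRUE)
  for (b in seq_len(p$n_branches)) {
    gs <- fate_genes[[b]]
    ## onsets concentrated near the root: fate identity emerges as soon
    ## as cells leave the progenitor state, as in the observed continuum
    onset <- stats::rbeta(length(gs), 1, 3) * 0.9 * p$branch_length
    width <- runif(length(gs), width_rng[1], width_rng[2])
    eff <- p$fate_effect * runif(length(gs), 0.6, 1.4)
    cells_b <- which(branch == b)
    for (i in seq_along(gs)) {
      log_mu[gs[i], cells_b] <- log_mu[gs[i], cells_b] +
        eff[i] * logistic_ramp(pt[cells_b], onset[i], width[i], p$branch_length)
    }
    fate_programs[[b]] <- data.frame(gene = gene_ids[gs], effect = eff,
                                     onset = onset, width = width)
  }
  names(fate_programs) <- paste0("fate", seq_len(p$n_branches))

  ## mitotic subpopulation
  mito_genes <- seq(p$n_branches * p$n_fate_genes + 1L,
                    length.out = p$n_mitotic_genes)
  n_mito <- round(p$mitotic_fraction * nC)
  mitotic <- rep(FALSE, nC)
  if (n_mito > 0) {
    mitotic[sample.int(nC, n_mito)] <- TRUE
    mito_eff <- p$mitotic_effect * runif(p$n_mitotic_genes, 0.7, 1.3)
    log_mu[mito_genes, mitotic] <- log_mu[mito_genes, mitotic] + mito_eff
  }

  ## planted independent components, progenitor-restricted
  src_mask <- if (p$progenitor_only) rep(TRUE, nC) else progenitor
  planted <- plant_independent_sources(
    log_mu, p$n_planted_sources, src_mask,
    n_source_genes = p$n_source_genes, effect = p$source_effect,
    p_active = p$source_p_active,
    avoid_genes = c(unlist(fate_genes), mito_genes))
  log_mu <- planted$log_means

  counts <- matrix(rnbinom(nG * nC, mu = exp(log_mu),
                           size = rep(size, nC)), nG, nC)
  dimnames(counts) <- list(gene_ids, cell_ids)
  dimnames(log_mu) <- list(gene_ids, cell_ids)
  dimnames(planted$loadings) <- list(cell_ids, NULL)
  dimnames(planted$weights) <- list(gene_ids, NULL)
  dataset_tag(counts) <- "platform1"

  truth <- list(
    cell_branch = setNames(paste0("fate", branch), cell_ids),
    cell_pseudotime = setNames(pt / p$branch_length, cell_ids),
    progenitor = setNames(progenitor, cell_ids),
    mitotic = setNames(mitotic, cell_ids),
    fate_programs = fate_programs,
    mitotic_genes = gene_ids[mito_genes],
    planted_loadings = planted$loadings,
    planted_weights = planted$weights,
    lib_factor = setNames(libf, cell_ids),
    log_mu = log_mu,
    nb_size = setNames(size, gene_ids),
    params = p)
  list(counts = counts, truth = truth)
}

#' Simulate a second-platform replicate of an existing simulation
#'
#' Re-draws negative-binomial counts from the same gene/cell log-means
#' with library sizes rescaled (default 0.2x), emulating a lower-depth
#' platform so two-dataset marker filters can be exercised.
#'
#' @param sim output of [simulate_tree_counts()]
#' @param lib_scale depth multiplier
#' @param seed seed for the redraw
#' @return counts matrix tagged `"platform2"`
#' @export
simulate_platform_replicate <- function(sim, lib_scale = NULL, seed = NULL) {
  p <- sim$truth$params
  if (is.null(lib_scale)) lib_scale <- p$platform_lib_scale
  if (is.null(seed)) seed <- derive_seed(p$seed, "platform2")
  set.seed(seed)
  mu <- exp(sim$truth$log_mu + log(lib_scale))
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = rep(sim$truth$nb_size, ncol(mu))),
                   nrow(mu), ncol(mu), dimnames = dimnames(sim$truth$log_mu))
  dimnames(counts) <- dimnames(sim$counts)
  dataset_tag(counts) <- "platform2"
  counts
}

#' Simulate a progenitor-only expression matrix with planted components
#'
#' Convenience wrapper for the progenitor-heterogeneity study: all cells
#' are drawn inside the progenitor pseudotime window of a single trunk,
#' before fate programs switch on, with the mitotic program disabled and
#' library depth held constant (the per-cell normalization applied ahead
#' of ICA removes depth anyway), so the planted independent sources are
#' the only multi-gene structure above gene-wise noise — the
#' configuration whose components the stability-selected ICA is meant to
#' recover.
#'
#' @param params list from [sim_params()]; `n_branches`,
#'   `progenitor_only`, `fate_effect`, `mitotic_fraction` and
#'   `lib_sdlog` are overridden
#' @return as [simulate_tree_counts()]
#' @export
simulate_progenitor_counts <- function(params = sim_params()) {
  params$n_branches <- 1L
  params$progenitor_only <- TRUE
  params$fate_effect <- 0
  params$mitotic_fraction <- 0
  params$lib_sdlog <- 0
  simulate_tree_counts(params)
}
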