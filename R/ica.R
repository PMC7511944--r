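#' Standardize an expression matrix for ICA
#'
#' Retains the most overdispersed genes (per-gene sd of variance-
#' adjusted expression above `gene_sd_min`, study cut 0.9) and scales
#' each retained gene to zero mean and unit sd across cells.
#'
#' @param expr fpm matrix (genes x cells)
#' @param gene_sd_min overdispersion threshold (`-Inf` keeps all genes)
#' @param overdispersion optional named per-gene scores; computed via
#'   [variance_adjust()] when absent
#' @return standardized genes x cells matrix
#' @export
standardize_for_ica <- function(expr, gene_sd_min = 0.9,
                                overdispersion = NULL) {
  x <- as_dense(expr)
  if (is.null(overdispersion)) overdispersion <- attr(expr, "overdispersion")
  if (is.finite(gene_sd_min)) {
    if (is.null(overdispersion))
      overdispersion <- attr(variance_adjust(x), "overdispersion")
    x <- x[overdispersion[rownames(x)] > gene_sd_min, , drop = FALSE]
  }
  sds <- apply(x, 1, sd)
  keep <- sds > 0
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stopf("fewer than 2 variable genes retained for ICA")
  out <- (x - rowMeans(x)) / sds[keep]
  dataset_tag(out) <- dataset_tag(expr)
  out
}

#' Gene-shuffled control matrix
#'
#' Permutes each gene's values independently across cells, destroying
#' gene-gene covariation while preserving each gene's marginal exactly.
#'
#' @param mat genes x cells matrix
#' @param seed integer seed
#' @return shuffled matrix of the same dimensions
#' @export
shuffle_control <- function(mat, seed = 1L) {
  x <- as_dense(mat)
  set.seed(seed)
  out <- t(apply(x, 1, sample))
  dimnames(out) <- dimnames(x)
  out
}

#' Run ICA on a standardized expression matrix
#'
#' Fast fixed-point ICA (`ica::icafast`) with cells as observations, so
#' components are independent axes of cell-to-cell variability; the
#' mixing matrix carries per-gene weights. By default the fixed-point
#' search runs once from the PCA basis (deterministic); with
#' `restarts > 1` it is additionally restarted from seeded random
#' rotations (whitening is shared, so restarts are cheap) and the
#' solution with the highest total negentropy is kept, guarding
#' against poor local optima. Failed attempts are always retried with
#' fresh derived seeds. Components are ordered by variance accounted
#' for and sign-oriented so each component's largest-magnitude gene
#' weight is positive.
#'
#' @param mat standardized genes x cells matrix
#' @param nc number of components (default 20)
#' @param seed integer seed
#' @param maxit,tol fixed-point controls
#' @param restarts solutions to compare (default 1)
#' @param init `"pca"` starts the first attempt from the PCA basis
#'   (deterministic); `"random"` uses a seeded random rotation for every
#'   attempt
#' @return list: `S` (cells x nc cell scores), `M` (genes x nc gene
#'   weights), `vafs`, `nc`, `seed`
#' @export
run_ica <- function(mat, nc = 20L, seed = 1L, maxit = 200L, tol = 1e-7,
                    restarts = 1L, init = c("pca", "random")) {
  init <- match.arg(init)
  x <- t(as_dense(mat))                     # cells x genes
  if (nc > min(dim(x))) stopf("nc (%d) exceeds min matrix dimension", nc)
  n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  ## whiten in the (smaller) cell dimension: top-nc eigenvectors of the
  ## cell-cell Gram matrix give the PC scores icafast would compute from
  ## a full SVD, at a fraction of the cost
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  Zw <- ev$vectors[, seq_len(nc), drop = FALSE] * sqrt(n - 1)
  ## negentropy proxy (log-cosh contrast; 0.3746 is its Gaussian value)
  negent <- function(S) sum((colMeans(log(cosh(S))) - 0.37457)^2)
  res <- NULL; best_ne <- -Inf; n_ok <- 0L
  for (try in seq_len(max(restarts, 1L) + 4L)) {
    ## first attempt from the PCA basis (deterministic), then random
    ## orthogonal rotations
    R0 <- if (try == 1 && init == "pca") diag(nc) else {
      set.seed(derive_seed(seed, paste0("ica", try)))
      qr.Q(qr(matrix(rnorm(nc * nc), nc)))
    }
    cand <- tryCatch(ica::icafast(Zw, nc = nc, center = FALSE,
                                  maxit = maxit, tol = tol, Rmat = R0),
                     error = function(e) NULL)
    if (is.null(cand) || !all(is.finite(cand$S))) next
    n_ok <- n_ok + 1L
    ne <- negent(cand$S)
    if (ne > best_ne) { best_ne <- ne; res <- cand }
    if (n_ok >= restarts) break
  }
  if (is.null(res)) stopf("ICA failed to converge after retries")
  S <- res$S
  M <- crossprod(x, S) / (n - 1)            # gene weights
  ## order by variance accounted for (gene-weight energy)
  ord <- order(colSums(M^2), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]; M <- M[, ord, drop = FALSE]
  ## deterministic orientation: largest-|weight| gene positive
  for (k in seq_len(ncol(M))) {
    j <- which.max(abs(M[, k]))
    if (M[j, k] < 0) { M[, k] <- -M[, k]; S[, k] <- -S[, k] }
  }
  rownames(S) <- colnames(mat)
  rownames(M) <- rownames(mat)
  vafs <- colSums(M^2) / (sum(x^2) / (n - 1))
  list(S = S, M = M, vafs = vafs, nc = nc, seed = seed)
}

#' Subsampling stability of independent components
#'
#' Runs ICA once on the full matrix (deterministic PCA-basis start) and
#' on `runs` random subsamples of `fraction` of the cells (without
#' replacement; single seeded random initialization each, so a
#' subsample reproduces a component only if the component is a genuine
#' attractor of the data rather than an artifact of one starting
#' point); each full-matrix component is matched to the most
#' similar subsample component by absolute Pearson correlation of
#' gene-weight vectors, and its stability is the mean best |correlation|
#' over runs.
#'
#' @param mat standardized genes x cells matrix
#' @param nc components (default 20)
#' @param runs subsample runs (default 100)
#' @param fraction cell fraction per run (default 0.7)
#' @param seed integer seed
#' @return numeric per-component stability in [0, 1]; full-matrix ICA in
#'   attribute `ica`, per-run best correlations in attribute `matches`
#' @export
component_stability <- function(mat, nc = 20L, runs = 100L, fraction = 0.7,
                                seed = 1L) {
  if (runs < 2) stopf("runs must be >= 2")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  n <- ncol(mat)
  n_sub <- floor(fraction * n)
  if (n_sub < nc) stopf("subsample size (%d) smaller than nc (%d)", n_sub, nc)
  full <- run_ica(mat, nc = nc, seed = derive_seed(seed, "full"))
  best <- matrix(NA_real_, runs, nc)
  for (r in seq_len(runs)) {
    set.seed(derive_seed(seed, paste0("sub", r)))
    cells <- sample.int(n, n_sub)
    sub <- run_ica(mat[, cells, drop = FALSE], nc = nc,
                   seed = derive_seed(seed, paste0("icasub", r)),
                   restarts = 1L, init = "random")
    cc <- abs(suppressWarnings(cor(full$M, sub$M)))
    cc[!is.finite(cc)] <- 0
    best[r, ] <- apply(cc, 1, max)
  }
  stab <- colMeans(best)
  structure(stab, ica = full, matches = best)
}

#' Select stable components against a shuffled control
#'
#' Components whose stability exceeds the chosen summary of the control
#' stabilities (maximum by default, or the 95th percentile) are called
#' stable. When the standardized matrix is supplied, ICA is re-run with
#' `nc = |stable set|` and those final components are returned.
#'
#' @param data_stab stability vector of the data matrix
#' @param control_stab stability vector of the shuffled control
#' @param rule `"above_control_max"` (default) or `"above_control_q95"`
#' @param mat optional standardized matrix for the final re-run
#' @param seed seed for the final re-run
#' @return list: `stable` (component indices), `threshold`, `rule`,
#'   `final` (re-run ICA or NULL)
#' @export
select_stable_components <- function(data_stab, control_stab,
                                     rule = c("above_control_max",
                                              "above_control_q95"),
                                     mat = NULL, seed = 1L) {
  rule <- match.arg(rule)
  if (length(data_stab) != length(control_stab))
    stopf("stability vectors must have equal length (same nc)")
  thr <- switch(rule,
                above_control_max = max(control_stab),
                above_control_q95 = quantile(control_stab, 0.95, names = FALSE))
  stable <- which(data_stab > thr)
  if (!length(stable)) warnf("no components exceed the control stability")
  final <- NULL
  if (!is.null(mat) && length(stable))
    final <- run_ica(mat, nc = length(stable),
                     seed = derive_seed(seed, "final"), restarts = 5L)
  list(stable = stable, threshold = thr, rule = rule, final = final)
}

#' End-to-end stability-selected ICA
#'
#' The full procedure: gene-shuffled control, component stability for
#' data and control (identical settings), stable-set selection, and a
#' final ICA re-run at the selected dimensionality.
#'
#' @param mat standardized genes x cells matrix
#' @param nc,runs,fraction stability settings (defaults 20 / 100 / 0.7)
#' @param rule selection rule (see [select_stable_components()])
#' @param seed integer seed
#' @return list: `stability`, `control_stability`, `stable`,
#'   `threshold`, `final`, `ica` (full-matrix run), settings
#' @export
ica_stability_analysis <- function(mat, nc = 20L, runs = 100L,
                                   fraction = 0.7,
                                   rule = "above_control_max", seed = 1L) {
  control <- shuffle_control(mat, seed = derive_seed(seed, "shuffle"))
  stab <- component_stability(mat, nc, runs, fraction,
                              seed = derive_seed(seed, "data"))
  ctrl_stab <- component_stability(control, nc, runs, fraction,
                                   seed = derive_seed(seed, "control"))
  sel <- select_stable_components(as.numeric(stab), as.numeric(ctrl_stab),
                                  rule = rule, mat = mat, seed = seed)
  list(stability = as.numeric(stab),
       control_stability = as.numeric(ctrl_stab),
       stable = sel$stable, threshold = sel$threshold,
       final = sel$final, ica = attr(stab, "ica"),
       nc = nc, runs = runs, fraction = fraction, rule = rule, seed = seed)
}
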