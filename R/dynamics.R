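#' Fit smooth gene dynamics along pseudotime
#'
#' Models each gene's fpm as a penalized degree-5 B-spline of pseudotime
#' (`mgcv::gam`, smoothness by GCV), evaluates the fitted curve on a
#' regular grid spanning the observed pseudotime, and records the
#' expression magnitude (max - min of the fitted curve, log10 units),
#' the smooth-term p value, its Benjamini-Hochberg adjustment across
#' genes, and the peak pseudotime.
#'
#' @param expr fpm matrix (genes x cells)
#' @param pt per-cell pseudotime (named; matched to columns)
#' @param degree spline degree (default 5)
#' @param grid_n grid resolution (default 100)
#' @param k basis dimension passed to `mgcv::s` (default 10)
#' @return object of class `dynamics_fit`: `stats` data.frame (gene,
#'   magnitude, p_raw, p_adj, peak_pseudotime), `curves` (genes x grid),
#'   `grid`
#' @export
fit_gene_dynamics <- function(expr, pt, degree = 5L, grid_n = 100L, k = 10L) {
  x <- as_dense(expr)
  if (!is.null(names(pt)) && !is.null(colnames(x))) {
    common <- intersect(colnames(x), names(pt))
    if (length(common) < 20) stopf("fewer than 20 cells with pseudotime")
    x <- x[, common, drop = FALSE]
    pt <- pt[common]
  }
  if (length(unique(pt)) < 2) stopf("pseudotime is constant")
  if (ncol(x) < 20) stopf("gene dynamics need >= 20 cells")
  grid <- seq(min(pt), max(pt), length.out = grid_n)
  nd <- data.frame(t = grid)
  genes <- rownames(x)
  curves <- matrix(NA_real_, nrow(x), grid_n,
                   dimnames = list(genes, NULL))
  p_raw <- magnitude <- peak <- rep(NA_real_, nrow(x))
  tvec <- as.numeric(pt)
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    if (sd(y) == 0) {
      curves[i, ] <- y[1]; magnitude[i] <- 0; p_raw[i] <- 1
      peak[i] <- grid[1]
      next
    }
    fit <- tryCatch(
      mgcv::gam(y ~ s(t, bs = "bs", m = c(degree, 2), k = k),
                data = data.frame(y = y, t = tvec), method = "GCV.Cp"),
      error = function(e) NULL)
    if (is.null(fit)) {
      ## degenerate design: fall back to linear fit
      lf <- lm(y ~ tvec)
      curves[i, ] <- coef(lf)[1] + coef(lf)[2] * grid
      p_raw[i] <- summary(lf)$coefficients[2, 4]
    } else {
      curves[i, ] <- as.numeric(stats::predict(fit, newdata = nd))
      st <- summary(fit)$s.table
      p_raw[i] <- if (nrow(st)) st[1, "p-value"] else 1
      if (!is.finite(p_raw[i])) {
        ## a (near-)perfect fit of a non-constant trend leaves no
        ## residual variance for the test; call it maximally significant
        res_var <- var(y - stats::fitted(fit))
        p_raw[i] <- if (res_var < 1e-12 * var(y)) 0 else 1
      }
    }
    magnitude[i] <- max(curves[i, ]) - min(curves[i, ])
    peak[i] <- grid[which.max(curves[i, ])]
  }
  p_raw[!is.finite(p_raw)] <- 1
  p_raw <- pmin(pmax(p_raw, 0), 1)
  stats_df <- data.frame(gene = genes, magnitude = magnitude,
                         p_raw = p_raw,
                         p_adj = p.adjust(p_raw, method = "BH"),
                         peak_pseudotime = peak,
                         stringsAsFactors = FALSE)
  structure(list(stats = stats_df, curves = curves, grid = grid,
                 degree = degree), class = "dynamics_fit")
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat(sprintf("dynamics_fit: %d genes on a %d-point pseudotime grid\n",
              nrow(x$stats), length(x$grid)))
  invisible(x)
}

#' Filter dynamically expressed genes
#'
#' `mode = "fold"` keeps genes whose fitted magnitude exceeds
#' `log10(min_fold)` (a 100-fold change on the fpm scale is a magnitude
#' of 2.0); `mode = "fpm"` thresholds the magnitude directly (e.g. more
#' than 1 fpm difference along PC1). Both magnitude and adjusted-p
#' comparisons are strict (`>` and `<`).
#'
#' @param fits `dynamics_fit`
#' @param min_fold fold threshold (fold mode, default 100)
#' @param max_p_adj adjusted p threshold (default 1e-5)
#' @param mode `"fold"` or `"fpm"`
#' @param min_fpm magnitude threshold in fpm units (fpm mode, default 1)
#' @return character vector of passing gene ids
#' @export
filter_dynamic_genes <- function(fits, min_fold = 100, max_p_adj = 1e-5,
                                 mode = c("fold", "fpm"), min_fpm = 1) {
  mode <- match.arg(mode)
  s <- fits$stats
  thr <- if (mode == "fold") log10(min_fold) else min_fpm
  s$gene[s$magnitude > thr & s$p_adj < max_p_adj]
}

#' Cluster dynamic genes into expression modules
#'
#' Standardizes each gene's fitted curve (zero mean, unit sd), then
#' hierarchical clustering with Ward linkage on Euclidean distances,
#' cut into `n_modules` modules (the study uses nine).
#'
#' @param fits `dynamics_fit`
#' @param genes character vector of genes to cluster
#' @param n_modules number of modules (default 9)
#' @return named integer vector gene -> module id, with the `hclust`
#'   object in attribute `hclust`
#' @export
cluster_gene_modules <- function(fits, genes, n_modules = 9L) {
  genes <- intersect(genes, rownames(fits$curves))
  if (n_modules > length(genes))
    stopf("n_modules (%d) exceeds number of genes (%d)", n_modules, length(genes))
  cur <- fits$curves[genes, , drop = FALSE]
  sds <- apply(cur, 1, sd)
  sds[sds == 0] <- 1
  z <- (cur - rowMeans(cur)) / sds
  hc <- hclust(dist(z), method = "ward.D2")
  modules <- cutree(hc, k = n_modules)
  structure(modules, hclust = hc)
}

#' Order genes for pseudotime heatmaps
#'
#' Primary key: pseudotime of maximum fitted expression. With
#' `scheme = "peak_then_rise"` ties (and near-ties within one grid step)
#' are broken by the earliest grid point at which the fitted derivative
#' exceeds the gene's magnitude-to-pseudotime-range ratio (the steep-
#' rise point), then by gene id.
#'
#' @param fits `dynamics_fit`
#' @param genes genes to order
#' @param scheme `"peak"` or `"peak_then_rise"`
#' @return ordered character vector of gene ids
#' @export
order_genes_for_heatmap <- function(fits, genes,
                                    scheme = c("peak", "peak_then_rise")) {
  scheme <- match.arg(scheme)
  genes <- intersect(genes, fits$stats$gene)
  s <- fits$stats[match(genes, fits$stats$gene), ]
  if (scheme == "peak") {
    return(genes[order(s$peak_pseudotime, s$gene)])
  }
  grid <- fits$grid
  dt <- diff(grid)[1]
  rng <- max(grid) - min(grid)
  rise <- vapply(genes, function(g) {
    cur <- fits$curves[g, ]
    dcur <- diff(cur) / dt
    thr <- (max(cur) - min(cur)) / rng
    hit <- which(dcur > thr)
    if (length(hit)) grid[hit[1]] else max(grid)
  }, numeric(1))
  genes[order(s$peak_pseudotime, rise, s$gene)]
}

#' Detect a sharp transition along pseudotime
#'
#' Single change-point scan: orders a per-cell summary (e.g. mean module
#' expression) by pseudotime and finds the split maximizing the
#' normalized between-segment mean difference
#' `|mean_left - mean_right| * sqrt(n_l * n_r / n^2)`. The split is
#' reported as a transition only if a Welch t-test at the best split is
#' significant (`p < alpha`); flat profiles return `transition = FALSE`.
#'
#' @param values per-cell numeric summary
#' @param pt per-cell pseudotime
#' @param min_seg minimum cells per segment (default 5)
#' @param alpha significance cutoff for calling a transition (default 1e-3)
#' @return list: `transition` (logical), `pseudotime`, `statistic`,
#'   `p_value`
#' @export
detect_transition_point <- function(values, pt, min_seg = 5L, alpha = 1e-3) {
  if (length(values) != length(pt)) stopf("values and pt differ in length")
  if (length(values) < 2 * min_seg) stopf("too few cells for change-point scan")
  o <- order(pt)
  v <- values[o]; t_ <- pt[o]
  n <- length(v)
  if (sd(v) == 0)
    return(list(transition = FALSE, pseudotime = NA_real_,
                statistic = 0, p_value = 1))
  cums <- cumsum(v); tot <- cums[n]
  ks <- seq(min_seg, n - min_seg)
  m1 <- cums[ks] / ks
  m2 <- (tot - cums[ks]) / (n - ks)
  stat <- abs(m1 - m2) * sqrt(ks * (n - ks)) / n
  best <- ks[which.max(stat)]
  pval <- tryCatch(t.test(v[seq_len(best)], v[seq(best + 1, n)])$p.value,
                   error = function(e) 1)
  list(transition = is.finite(pval) && pval < alpha,
       pseudotime = (t_[best] + t_[best + 1]) / 2,
       statistic = max(stat), p_value = pval)
}
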