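#' Filter cells by number of detected genes
#'
#' Removes cells with fewer than `min_genes` genes detected (count > 0).
#' "Fewer than" is strict: a cell with exactly `min_genes` detected genes
#' is kept. Survivor order is preserved.
#'
#' @param counts gene-by-cell count matrix
#' @param min_genes detection threshold (default 800)
#' @return filtered count matrix
#' @export
filter_cells <- function(counts, min_genes = 800L) {
  check_counts(counts)
  if (min_genes < 0) stopf("min_genes must be >= 0")
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= min_genes
  if (!any(keep)) stopf("all %d cells removed by min_genes=%d filter",
                        ncol(counts), min_genes)
  out <- counts[, keep, drop = FALSE]
  dataset_tag(out) <- dataset_tag(counts)
  out
}

#' Filter genes by read support across cells
#'
#' Keeps genes having at least `min_reads` reads in at least `min_cells`
#' cells (both inclusive).
#'
#' @param counts gene-by-cell count matrix
#' @param min_reads per-cell read threshold (default 60)
#' @param min_cells number of cells that must reach it (default 30)
#' @return filtered count matrix
#' @export
filter_genes <- function(counts, min_reads = 60L, min_cells = 30L) {
  check_counts(counts)
  if (min_reads < 0 || min_cells < 0) stopf("thresholds must be >= 0")
  support <- Matrix::rowSums(counts >= min_reads)
  keep <- support >= min_cells
  if (!any(keep)) stopf("all genes removed by gene filter")
  out <- counts[keep, , drop = FALSE]
  dataset_tag(out) <- dataset_tag(counts)
  out
}

#' Normalize counts to fpm (per-cell mean-normalized, log10)
#'
#' For each cell j, `fpm(g, j) = log10(1 + count(g, j) / mean_g count(g, j))`
#' — expression normalized per mean expression level in every cell, then
#' log10-transformed with pseudocount 1 (recorded in provenance). The
#' result is invariant to rescaling any cell's counts.
#'
#' @param counts gene-by-cell count matrix
#' @param pseudocount added inside the log (default 1)
#' @return fpm matrix (dense) with provenance attribute
#' @export
normalize_fpm <- function(counts, pseudocount = 1) {
  check_counts(counts)
  x <- as_dense(counts)
  cm <- colMeans(x)
  if (any(cm == 0)) stopf("all-zero cell(s) present; filter cells first")
  fpm <- log10(pseudocount + sweep(x, 2, cm, "/"))
  attr(fpm, "provenance") <-
    c(provenance(counts),
      sprintf("normalize_fpm(pseudocount=%g)", pseudocount))
  dataset_tag(fpm) <- dataset_tag(counts)
  fpm
}

#' Adjust expression for the variance-mean trend
#'
#' Fits a loess trend of log gene variance against mean expression,
#' rescales each gene's centered expression by the trend-predicted sd,
#' and scores each gene's overdispersion as the sd of its adjusted
#' values (1 = on trend). The score drives overdispersed-gene filters
#' such as "sd of variance-adjusted expression > 0.9".
#'
#' @param expr fpm matrix (genes x cells)
#' @param span loess span (default 0.5)
#' @return adjusted matrix with attributes `overdispersion` (named
#'   per-gene score) and provenance
#' @export
variance_adjust <- function(expr, span = 0.5) {
  x <- as_dense(expr)
  if (nrow(x) < 10) stopf("variance adjustment needs >= 10 genes")
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  if (all(v == 0)) stopf("constant expression matrix")
  pos <- v > 0
  fit <- stats::loess(log(v[pos]) ~ mu[pos], span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  pred_sd <- sqrt(exp(stats::predict(fit, newdata = data.frame(mu = mu))))
  pred_sd[!is.finite(pred_sd) | pred_sd <= 0] <- min(pred_sd[pred_sd > 0 & is.finite(pred_sd)])
  adj <- (x - mu) / pred_sd
  od <- apply(adj, 1, sd)
  names(od) <- rownames(x)
  attr(adj, "overdispersion") <- od
  attr(adj, "provenance") <- c(provenance(expr),
                               sprintf("variance_adjust(span=%g)", span))
  dataset_tag(adj) <- dataset_tag(expr)
  adj
}

#' Score cells against a gene signature
#'
#' `method = "mean"`: per-cell average fpm over the signature genes
#' present in the matrix. `method = "pc1"`: first principal component of
#' cells in the signature-gene subspace, sign-oriented so it correlates
#' positively with the mean score and centered at zero.
#'
#' @param expr fpm matrix
#' @param gene_set character vector of gene ids, or a `list(name, genes)`
#'   as from [read_gene_sets()]
#' @param method `"mean"` or `"pc1"`
#' @return numeric per-cell score with attributes `gene_set`, `method`
#' @export
score_signature <- function(expr, gene_set, method = c("mean", "pc1")) {
  method <- match.arg(method)
  x <- as_dense(expr)
  set_name <- "signature"
  if (is.list(gene_set)) {
    set_name <- gene_set$name %||% set_name
    gene_set <- gene_set$genes
  }
  present <- intersect(gene_set, rownames(x))
  if (!length(present)) {
    stopf("no signature genes present in matrix; missing: %s",
          paste(head(setdiff(gene_set, rownames(x)), 10), collapse = ", "))
  }
  sub <- x[present, , drop = FALSE]
  score <- if (method == "mean") {
    colMeans(sub)
  } else {
    if (ncol(sub) < 3) stopf("pc1 scoring needs >= 3 cells")
    pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
    s <- pc$x[, 1]
    m <- colMeans(sub)
    if (sd(m) > 0 && cor(s, m) < 0) s <- -s
    s
  }
  names(score) <- colnames(x)
  structure(score, gene_set = set_name, method = method,
            n_genes = length(present))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regress a signature score out of expression
#'
#' Replaces every gene by the residuals of a least-squares fit on
#' (intercept, score), re-centered to the gene's original mean so fpm
#' values keep their interpretation. A constant score leaves the matrix
#' unchanged with a warning.
#'
#' @param expr fpm matrix
#' @param score per-cell signature score (length = n cells)
#' @return corrected matrix, provenance appended
#' @export
regress_out_signature <- function(expr, score) {
  x <- as_dense(expr)
  if (length(score) != ncol(x)) stopf("score length != number of cells")
  if (sd(score) == 0) {
    warnf("constant signature score; expression left unchanged")
    return(add_provenance(x, "regress_out_signature(constant score)"))
  }
  s <- score - mean(score)
  beta <- (x %*% s) / sum(s * s)          # per-gene slope
  out <- x - beta %*% t(s)                # residuals + original gene means
  dimnames(out) <- dimnames(x)
  attr(out, "provenance") <- c(provenance(expr), "regress_out_signature")
  dataset_tag(out) <- dataset_tag(expr)
  out
}

#' Remove admixed/outlier cells by neighbourhood correlation
#'
#' For each cell, computes Pearson correlations to all other cells and
#' keeps cells whose mean correlation over their `k` most-correlated
#' peers exceeds `min_mean_cor` (cells with mean correlation of more
#' than 0.2 to their 200 most correlated cells are retained, by
#' default). Correlations are computed on the `n_top` most overdispersed
#' genes when the matrix is larger than that (set `n_top = Inf` for all
#' genes).
#'
#' @param expr fpm matrix
#' @param k neighbourhood size (default 200)
#' @param min_mean_cor retention threshold (default 0.2)
#' @param n_top gene subset size for the correlations (default 3000)
#' @return filtered expression matrix; removed cells in attribute
#'   `removed`
#' @export
admixture_cleanup <- function(expr, k = 200L, min_mean_cor = 0.2,
                              n_top = 3000L) {
  x <- as_dense(expr)
  n <- ncol(x)
  if (k >= n) stopf("k (%d) must be smaller than number of cells (%d)", k, n)
  g <- x
  if (is.finite(n_top) && nrow(x) > n_top) {
    od <- attr(expr, "overdispersion")
    if (is.null(od)) od <- attr(variance_adjust(x), "overdispersion")
    g <- x[order(od, decreasing = TRUE)[seq_len(n_top)], , drop = FALSE]
  }
  cc <- suppressWarnings(cor(g))
  diag(cc) <- NA
  mean_top <- apply(cc, 2, function(col) {
    v <- sort(col[!is.na(col)], decreasing = TRUE)
    mean(v[seq_len(min(k, length(v)))])
  })
  keep <- mean_top > min_mean_cor
  if (!any(keep)) stopf("admixture cleanup removed all cells")
  out <- x[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(x)[!keep]
  attr(out, "provenance") <- c(provenance(expr),
                               sprintf("admixture_cleanup(k=%d,min_mean_cor=%g)",
                                       k, min_mean_cor))
  dataset_tag(out) <- dataset_tag(expr)
  out
}
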