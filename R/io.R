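#' Read a gene-by-cell count matrix
#'
#' Reads either a 10x-style MTX triplet (a directory holding `matrix.mtx`,
#' `features.tsv` and `barcodes.tsv`) or a dense TSV with gene rows, cell
#' columns and a header line of cell ids. The returned matrix always has
#' genes as rows and cells as columns regardless of on-disk orientation,
#' with unique gene rownames and cell colnames; small dense matrices stay
#' dense, sparse ones are stored as `dgCMatrix`.
#'
#' @param path directory (mtx) or file (tsv)
#' @param format `"mtx"` or `"tsv"`; default guesses from `path`
#' @param dataset_tag label recorded on the matrix (platform/sample)
#' @return counts matrix (base matrix or `dgCMatrix`) with a
#'   `dataset_tag` attribute
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"),
                        dataset_tag = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx" else "tsv"
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stopf("missing MTX companion file: %s", f)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stopf("malformed MTX header in %s: %s",
                                            mtx, conditionMessage(e)))
    genes <- read.table(feat, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.table(bc, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (nrow(m) == length(cells) && ncol(m) == length(genes) &&
        length(genes) != length(cells)) {
      m <- Matrix::t(m)  # cell-major on disk
    }
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stopf("MTX dimensions (%d x %d) do not match features (%d) / barcodes (%d)",
            nrow(m), ncol(m), length(genes), length(cells))
    if (anyDuplicated(genes)) stopf("duplicate gene ids in %s", feat)
    if (anyDuplicated(cells)) stopf("duplicate cell ids in %s", bc)
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                      check.names = FALSE)
    m <- as.matrix(tab)
    if (anyDuplicated(rownames(m))) stopf("duplicate gene ids in %s", path)
    if (anyDuplicated(colnames(m))) stopf("duplicate cell ids in %s", path)
  }
  check_counts(m)
  dataset_tag(m) <- dataset_tag
  m
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: `"mtx"` writes the 10x triplet
#' (`matrix.mtx` + `features.tsv` + `barcodes.tsv`), `"tsv"` a dense
#' gene-by-cell table with header.
#'
#' @param counts gene-by-cell matrix with dimnames
#' @param path directory (mtx) or file (tsv)
#' @param format `"mtx"` or `"tsv"`
#' @export
write_counts <- function(counts, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  check_counts(counts)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(as_dense(counts), sparse = TRUE)
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "features.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene = rownames(counts), as_dense(counts),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets (GMT or one-set-per-line)
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the plain
#' `"list"` format is `name<TAB>gene1<TAB>gene2...`. Duplicated genes
#' within a set are dropped with a warning; an empty set is an error.
#'
#' @param path file path
#' @param format `"gmt"` (default) or `"list"`
#' @return list of gene sets, each `list(name=, genes=)`
#' @export
read_gene_sets <- function(path, format = c("gmt", "list")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("no gene sets in %s", path)
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "gmt") {
      if (length(f) < 3) stopf("GMT line with fewer than 3 fields: %s", ln)
      name <- f[1]; genes <- f[-(1:2)]
    } else {
      if (length(f) < 2) stopf("gene-set line with no genes: %s", ln)
      name <- f[1]; genes <- f[-1]
    }
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("empty gene set '%s'", name)
    if (anyDuplicated(genes)) {
      warnf("gene set '%s' contains duplicated genes; deduplicated", name)
      genes <- unique(genes)
    }
    list(name = name, genes = genes)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write gene sets as GMT
#'
#' @param sets list as returned by [read_gene_sets()], or a named list of
#'   character vectors
#' @param path output file
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(name = names(sets)[i], genes = s)
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
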