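#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd prcomp rnorm runif rbinom rgamma rnbinom
#'   quantile median t.test oneway.test pt p.adjust dist hclust cutree
#'   kmeans lm resid coef var aggregate setNames
#' @importFrom utils read.table write.table head packageVersion
#' @importFrom methods as
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Emit a structured log line
#'
#' Writes `[pulptree] <stage> | key=value ...` to stderr. Used by all
#' pipeline stages so runs are auditable.
#'
#' @param stage character stage name
#' @param ... named values echoed into the line
#' @export
pt_log <- function(stage, ...) {
  kv <- list(...)
  msg <- if (length(kv)) {
    paste(vapply(seq_along(kv), function(i) {
      paste0(names(kv)[i], "=", paste(format(kv[[i]]), collapse = ","))
    }, character(1)), collapse = " ")
  } else ""
  message(sprintf("[pulptree] %s | %s", stage, msg))
  invisible(NULL)
}

## dense coercion used internally; inputs may arrive as Matrix sparse
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

check_counts <- function(counts) {
  x <- as_dense(counts)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("count matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(x))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stopf("duplicate cell ids")
  if (any(!is.finite(x)) || any(x < 0)) stopf("counts must be finite and >= 0")
  invisible(TRUE)
}

## store sparse when it pays off (contract is values, not layout)
maybe_sparse <- function(x, density_cutoff = 0.3) {
  dens <- mean(x != 0)
  if (dens < density_cutoff) Matrix::Matrix(x, sparse = TRUE) else x
}

dataset_tag <- function(x) {
  tag <- attr(x, "dataset_tag")
  if (is.null(tag)) "default" else tag
}

`dataset_tag<-` <- function(x, value) {
  attr(x, "dataset_tag") <- value
  x
}

#' Provenance of a processed matrix
#'
#' Processing steps append themselves to a provenance attribute; this
#' accessor returns that record.
#'
#' @param x matrix produced by the preprocessing functions
#' @return character vector of applied steps (NULL if none)
#' @export
provenance <- function(x) attr(x, "provenance")

add_provenance <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}
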