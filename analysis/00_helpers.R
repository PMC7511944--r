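## shared by the numbered analysis drivers: rebuild the processed
## expression objects from the files 01_simulate.R wrote (cheap, and
## keeps every artifact plain text)

library(pulptree)

load_processed <- function() {
  counts <- read_counts("results/data/counts_platform1.tsv", "tsv")
  truth <- read.table("results/data/truth_cells.tsv", header = TRUE)
  rownames(truth) <- truth$cell
  sets <- read_gene_sets("results/data/truth_gene_sets.gmt")
  counts <- filter_cells(counts, min_genes = 800)
  counts <- filter_genes(counts, min_reads = 5, min_cells = 10)
  expr <- normalize_fpm(counts)
  mito <- score_signature(expr, sets$mitotic$genes, method = "mean")
  expr <- regress_out_signature(expr, mito)
  adj <- variance_adjust(expr)
  truth <- truth[colnames(expr), ]
  list(counts = counts, expr = expr, adjusted = adj, truth = truth,
       gene_sets = sets, mitotic_score = mito)
}
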