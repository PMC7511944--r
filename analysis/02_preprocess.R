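#!/usr/bin/env Rscript
## Filtering and normalization of the simulated dataset: detected-gene
## cell filter, read-support gene filter, fpm normalization, mitotic-
## signature regression, and the variance-mean adjustment whose
## overdispersion scores drive downstream gene selections.

library(pulptree)

counts <- read_counts("results/data/counts_platform1.tsv", "tsv")
truth <- read.table("results/data/truth_cells.tsv", header = TRUE)
sets <- read_gene_sets("results/data/truth_gene_sets.gmt")

## thresholds scaled to the simulated depth (the deep-sequencing values
## of 60 reads / 30 cells refer to plate-based libraries)
counts <- filter_cells(counts, min_genes = 800)
counts <- filter_genes(counts, min_reads = 5, min_cells = 10)
expr <- normalize_fpm(counts)

mito <- score_signature(expr, sets$mitotic$genes, method = "mean")
expr <- regress_out_signature(expr, mito)
adj <- variance_adjust(expr)

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(cell = names(mito), mitotic_score = mito),
            "results/preprocess/mitotic_score.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
od <- attr(adj, "overdispersion")
write.table(data.frame(gene = names(od), overdispersion = od),
            "results/preprocess/overdispersion.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pt_log("02_preprocess", cells = ncol(expr), genes = nrow(expr),
       od_above_0.9 = sum(od > 0.9))
cat("Kept", ncol(expr), "cells and", nrow(expr), "genes;",
    sum(od > 0.9), "overdispersed genes (score > 0.9)\n")
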