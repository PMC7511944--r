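#!/usr/bin/env Rscript
## Generate the synthetic branched-differentiation dataset that every
## later step analyses: 800 cells on a three-armed tree (progenitor root
## at the centre), 1500 genes, a 10% mitotic subpopulation, five planted
## independent sources among progenitors, and a second platform at 0.2x
## depth. Writes counts and ground truth under results/data/.

library(pulptree)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
params <- sim_params(seed = 1L)
sim <- simulate_tree_counts(params)
rep2 <- simulate_platform_replicate(sim)

write_counts(sim$counts, "results/data/counts_platform1.tsv", "tsv")
write_counts(rep2, "results/data/counts_platform2.tsv", "tsv")
truth <- data.frame(cell = colnames(sim$counts),
                    branch = sim$truth$cell_branch,
                    pseudotime = sim$truth$cell_pseudotime,
                    progenitor = sim$truth$progenitor,
                    mitotic = sim$truth$mitotic)
write.table(truth, "results/data/truth_cells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
fate_sets <- lapply(names(sim$truth$fate_programs), function(f)
  list(name = f, genes = sim$truth$fate_programs[[f]]$gene))
write_gene_sets(c(fate_sets,
                  list(list(name = "mitotic", genes = sim$truth$mitotic_genes))),
                "results/data/truth_gene_sets.gmt")

pt_log("01_simulate",
       cells = ncol(sim$counts), genes = nrow(sim$counts),
       median_library = median(colSums(as.matrix(sim$counts))),
       mitotic = sum(sim$truth$mitotic))
cat("Simulated", ncol(sim$counts), "cells x", nrow(sim$counts), "genes;",
    "three branches of sizes",
    paste(table(sim$truth$cell_branch), collapse = "/"), "\n")
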