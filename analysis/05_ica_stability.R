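#!/usr/bin/env Rscript
## Progenitor heterogeneity by stability-selected ICA: a progenitor-only
## matrix with five planted independent non-Gaussian sources, 20
## components, 100 subsamplings of 70% of cells, and a gene-shuffled
## control; stable components are those above the control maximum, and
## the final decomposition is re-run at the selected dimensionality.

library(pulptree)

sim <- simulate_progenitor_counts(sim_params(seed = 1L))
expr <- normalize_fpm(sim$counts)
adj <- variance_adjust(expr)
mat <- standardize_for_ica(expr, gene_sd_min = 0.9,
                           overdispersion = attr(adj, "overdispersion"))
res <- ica_stability_analysis(mat, nc = 20, runs = 100, fraction = 0.7,
                              rule = "above_control_max",
                              seed = derive_seed(1L, "ica"))

match_r <- if (length(res$stable) && !is.null(res$final))
  apply(abs(cor(res$final$S, sim$truth$planted_loadings)), 2, max) else NULL

dir.create("results/ica", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(component = seq_along(res$stability),
                       stability = res$stability,
                       control_stability = res$control_stability,
                       stable = seq_along(res$stability) %in% res$stable),
            "results/ica/stability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (!is.null(res$final)) {
  write.table(data.frame(gene = rownames(res$final$M), res$final$M),
              "results/ica/final_gene_weights.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell = rownames(res$final$S), res$final$S),
              "results/ica/final_cell_scores.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(list(n_stable = length(res$stable),
                          threshold = res$threshold,
                          planted_recovery_r = match_r),
                     "results/ica/summary.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)

cat(length(res$stable), "of 20 components stable (control max =",
    round(res$threshold, 2), ");",
    if (!is.null(match_r))
      paste("planted sources recovered at |r| =",
            paste(round(match_r, 2), collapse = "/")) else "", "\n")
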