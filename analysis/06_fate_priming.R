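#!/usr/bin/env Rscript
## Fate-program priming analysis: 20-marker programs per fate from
## cluster-mean differences, per-cell program intensities, activity
## calls against the progenitor reference, pairwise exclusivity, the
## cell-cycle score, and the kNN projection of mitotic cells onto a
## non-mitotic embedding.

source("analysis/00_helpers.R")

pp <- load_processed()
truth <- pp$truth
cl <- ifelse(truth$progenitor, "progenitor", truth$branch)
names(cl) <- rownames(truth)
fates <- setdiff(unique(cl), "progenitor")

programs <- define_fate_markers(pp$expr, cl,
                                setNames(as.list(fates), fates),
                                "progenitor", n_markers = 20)
intensity <- vapply(programs, function(p) score_fate_intensity(pp$expr, p),
                    numeric(ncol(pp$expr)))
prog_cells <- names(cl)[cl == "progenitor"]
active <- vapply(colnames(intensity), function(f)
  as.logical(call_active_program(setNames(intensity[, f], colnames(pp$expr)),
                                 prog_cells)), logical(nrow(intensity)))
rownames(active) <- colnames(pp$expr)
priming <- priming_analysis(active)

## cell-cycle score and mitotic projection (PCA embedding of
## non-mitotic cells as the fallback 2D landscape)
cc <- score_signature(pp$expr, pp$gene_sets$mitotic$genes, method = "pc1")
coords <- prepare_space(pp$adjusted, "cosine", n_components = 20)
mito <- truth[rownames(coords), "mitotic"]
emb <- prcomp(coords[!mito, ])$x[, 1:2]
proj <- project_mitotic_cells(coords, mito, emb, k = 10)

dir.create("results/fates", showWarnings = FALSE, recursive = TRUE)
write_gene_sets(lapply(programs, function(p) list(name = p$fate, genes = p$genes)),
                "results/fates/programs.gmt")
write.table(data.frame(cell = rownames(active), intensity, active),
            "results/fates/intensity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(cell = rownames(proj$positions), proj$positions),
            "results/fates/mitotic_projection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(exclusivity = priming$exclusivity,
                          n_active = priming$n_active,
                          pairs = priming$pairs),
                     "results/fates/priming.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)

cat("Programs active in", priming$n_active, "cells; exclusivity =",
    round(priming$exclusivity, 3), "(1 = no multilineage priming);",
    nrow(proj$positions), "mitotic cells projected\n")
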