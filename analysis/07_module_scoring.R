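#!/usr/bin/env Rscript
## Cross-platform marker modules: two-group fold-change + t-test filters
## applied independently in both simulated platforms, intersection of
## the passing sets, cluster-enrichment table, module scoring across
## clusters, and similarity of cells to the mitotic group in a
## 30-component latent space.

source("analysis/00_helpers.R")

pp <- load_processed()
truth <- pp$truth
counts2 <- read_counts("results/data/counts_platform2.tsv", "tsv")
counts2 <- counts2[, colnames(pp$expr)]
expr2 <- normalize_fpm(counts2)

## apical-like vs distal-like committed cells, both platforms
committed <- rownames(truth)[!truth$progenitor &
                             truth$branch %in% c("fate2", "fate3")]
grp <- factor(truth[committed, "branch"], levels = c("fate2", "fate3"))
sets <- lapply(list(platform1 = pp$expr, platform2 = expr2), function(e) {
  two_group_markers(e[, committed], grp, fold_min = 3, p_max = 1e-10)
})
apical <- intersect_across_datasets(sets, name = "apical_like")

cl <- ifelse(truth$progenitor, "progenitor", truth$branch)
enrich <- cluster_enrichment_table(pp$expr, cl, fold_min = 4, p_max = 1e-10)
scores <- score_modules(pp$expr, cl,
                        list(apical_like = as.character(apical)))

lat <- prepare_space(pp$adjusted, "euclidean", n_components = 30)
simdiv <- similarity_to_group(lat, rownames(truth)[truth$mitotic])

dir.create("results/scoring", showWarnings = FALSE, recursive = TRUE)
write_gene_sets(list(apical_like = as.character(apical)),
                "results/scoring/markers.gmt")
jsonlite::write_json(attr(apical, "criteria"),
                     "results/scoring/marker_criteria.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
write.table(data.frame(cluster = rownames(scores), scores),
            "results/scoring/module_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enrich, "results/scoring/cluster_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cell = names(simdiv), similarity = simdiv),
            "results/scoring/similarity_to_dividing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(length(apical), "markers pass the 3-fold / p<1e-10 filter in both",
    "platforms;", nrow(enrich), "cluster-enriched genes;",
    "top-scoring cluster on the marker module:",
    rownames(scores)[which.max(scores[, 1])], "\n")
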