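stage_order <- c("simulate", "preprocess", "tree", "dynamics", "ica", "fates")

cfg_int <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) default else as.integer(v)
}

stage_deps <- list(
  simulate   = character(0),
  preprocess = "simulate",
  tree       = "preprocess",
  dynamics   = "tree",
  ica        = "preprocess",
  fates      = c("preprocess", "tree")
)

#' Run the analysis pipeline end to end
#'
#' Wires the stages (simulate -> preprocess -> tree -> dynamics / ica /
#' fates) into one reproducible run driven by a [default_config()]
#' snapshot. Every stage writes plain-text artifacts (TSV/JSON) under
#' `out_dir` and the run closes with a manifest recording the config,
#' per-stage seeds, stage order, file hashes, package version and
#' timestamps; re-running with the same config reproduces the artifacts
#' bitwise.
#'
#' @param config list from [default_config()]
#' @param stages ordered subset of
#'   `c("simulate","preprocess","tree","dynamics","ica","fates")`
#' @param out_dir output directory
#' @param state optional state list from a previous partial run (used to
#'   satisfy dependencies when running later stages alone)
#' @return invisible state list with all stage products and `manifest`
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "preprocess", "tree"),
                         out_dir = tempfile("pulptree_run_"),
                         state = list()) {
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- names(state)
  for (st in stages) {
    miss <- setdiff(stage_deps[[st]], c(done, stages[seq_len(match(st, stages) - 1)]))
    if (length(miss))
      stopf("stage '%s' requires missing artifact(s) from stage(s): %s",
            st, paste(miss, collapse = ", "))
  }
  t0 <- Sys.time()
  for (st in stages) {
    seed <- derive_seed(config$seed, st)
    pt_log(st, seed = seed)
    state <- switch(st,
      simulate = {
        sim <- simulate_tree_counts(sim_params(n_cells = cfg_int(config, "sim_n_cells", 800L),
                                               n_genes = cfg_int(config, "sim_n_genes", 1500L),
                                               seed = seed))
        write_counts(sim$counts, file.path(out_dir, "counts.tsv"), "tsv")
        truth_df <- data.frame(cell = colnames(sim$counts),
                               branch = sim$truth$cell_branch,
                               pseudotime = sim$truth$cell_pseudotime,
                               mitotic = sim$truth$mitotic)
        write.table(truth_df, file.path(out_dir, "truth_cells.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        c(state, list(simulate = sim))
      },
      preprocess = {
        sim <- state$simulate
        counts <- filter_genes(filter_cells(sim$counts, config$min_genes),
                               config$min_reads, config$min_cells)
        expr <- normalize_fpm(counts, config$fpm_pseudocount)
        adj <- variance_adjust(expr, config$variance_span)
        c(state, list(preprocess = list(counts = counts, expr = expr,
                                        adjusted = adj)))
      },
      tree = {
        pp <- state$preprocess
        coords <- prepare_space(pp$adjusted, config$distance, config$n_pcs)
        M <- min(config$M, floor(nrow(coords) / 2))
        tree <- fit_principal_tree(coords, config$lambda, config$sigma,
                                   M, config$tree_max_iter,
                                   config$tree_tol, seed = seed)
        truth <- state$simulate$truth
        prog <- names(truth$progenitor)[truth$progenitor]
        root <- select_root(tree, intersect(prog, rownames(coords)))
        pt <- assign_pseudotime(tree, root)
        br <- extract_branches(tree, config$prune_min_cells)
        out <- data.frame(cell = names(pt), pseudotime = as.numeric(pt),
                          branch = br$cell_branch[names(pt)],
                          node = tree$hard_assignment[names(pt)])
        write.table(out, file.path(out_dir, "pseudotime.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(edges = tree$edges, params = tree$params, root = root,
               n_branches = br$n_branches),
          file.path(out_dir, "tree.json"), auto_unbox = TRUE, digits = NA)
        c(state, list(tree = list(tree = tree, pseudotime = pt,
                                  branches = br, root = root,
                                  coords = coords)))
      },
      dynamics = {
        pp <- state$preprocess; tr <- state$tree
        fits <- fit_gene_dynamics(pp$expr, tr$pseudotime,
                                  degree = config$spline_degree,
                                  grid_n = config$dyn_grid)
        keep <- filter_dynamic_genes(fits, config$dyn_min_fold,
                                     config$dyn_max_p_adj)
        modules <- if (length(keep) >= config$n_modules)
          cluster_gene_modules(fits, keep, config$n_modules) else NULL
        write.table(fits$stats, file.path(out_dir, "dynamics.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        c(state, list(dynamics = list(fits = fits, dynamic_genes = keep,
                                      modules = modules)))
      },
      ica = {
        pp <- state$preprocess
        od <- attr(pp$adjusted, "overdispersion")
        mat <- standardize_for_ica(pp$expr, config$ica_sd_min, od)
        nc <- min(config$ica_nc, min(dim(mat)) - 1)
        res <- ica_stability_analysis(mat, nc, config$ica_runs,
                                      config$ica_fraction,
                                      config$ica_rule, seed = seed)
        write.table(data.frame(component = seq_len(nc),
                               stability = res$stability,
                               control_stability = res$control_stability,
                               stable = seq_len(nc) %in% res$stable),
                    file.path(out_dir, "ica_stability.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        c(state, list(ica = res))
      },
      fates = {
        pp <- state$preprocess; tr <- state$tree
        truth <- state$simulate$truth
        cl <- ifelse(truth$progenitor[colnames(pp$expr)], "progenitor",
                     truth$cell_branch[colnames(pp$expr)])
        fate_names <- setdiff(unique(cl), "progenitor")
        programs <- define_fate_markers(pp$expr, cl,
                                        setNames(as.list(fate_names), fate_names),
                                        "progenitor", config$n_markers)
        intensities <- vapply(programs, function(p)
          score_fate_intensity(pp$expr, p), numeric(ncol(pp$expr)))
        prog_cells <- colnames(pp$expr)[cl == "progenitor"]
        active <- vapply(seq_len(ncol(intensities)), function(j)
          as.logical(call_active_program(setNames(intensities[, j],
                                                  colnames(pp$expr)),
                                         prog_cells, config$active_n_sd)),
          logical(ncol(pp$expr)))
        colnames(active) <- colnames(intensities)
        priming <- priming_analysis(active)
        write_gene_sets(lapply(programs, function(p)
          list(name = p$fate, genes = p$genes)),
          file.path(out_dir, "fate_programs.gmt"))
        c(state, list(fates = list(programs = programs,
                                   intensity = intensities,
                                   active = active, priming = priming)))
      })
    done <- names(state)
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    config = unclass(config),
    stages = stages,
    stage_seeds = setNames(lapply(stages, function(s)
      derive_seed(config$seed, s)), stages),
    file_hashes = as.list(tools::md5sum(files)),
    version = as.character(utils::packageVersion("pulptree")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$manifest <- manifest
  state$out_dir <- out_dir
  invisible(state)
}
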