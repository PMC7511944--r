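make_cluster_fixture <- function() {
  ## 90 cells: 30 progenitor, 30 fate A (g1..g20 up), 30 fate B (g21..g40 up)
  set.seed(51)
  n_genes <- 60
  x <- matrix(rnorm(n_genes * 90, mean = 1, sd = 0.1), n_genes, 90,
              dimnames = list(paste0("g", 1:n_genes), paste0("c", 1:90)))
  x[1:20, 31:60] <- x[1:20, 31:60] + 2
  x[21:40, 61:90] <- x[21:40, 61:90] + 2
  cl <- rep(c("prog", "A", "B"), each = 30)
  names(cl) <- colnames(x)
  list(x = x, cl = cl)
}

test_that("fate markers are the largest-difference genes, disjoint across fates", {
  fx <- make_cluster_fixture()
  programs <- define_fate_markers(fx$x, fx$cl,
                                  list(A = "A", B = "B"), "prog", 20)
  expect_setequal(programs$A$genes, paste0("g", 1:20))
  expect_setequal(programs$B$genes, paste0("g", 21:40))
  expect_length(intersect(programs$A$genes, programs$B$genes), 0)

  ## single top marker
  p1 <- define_fate_markers(fx$x, fx$cl, list(A = "A"), "prog", 1)
  diffs <- rowMeans(fx$x[, fx$cl == "A"]) - rowMeans(fx$x[, fx$cl == "prog"])
  expect_equal(p1$A$genes, names(which.max(diffs)))

  ## brute-force agreement on a random matrix without shared top genes
  set.seed(8)
  y <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:60)))
  cl2 <- setNames(rep(c("p", "f"), each = 30), colnames(y))
  pf <- define_fate_markers(y, cl2, list(f = "f"), "p", 5)
  d <- rowMeans(y[, 31:60]) - rowMeans(y[, 1:30])
  expect_setequal(pf$f$genes, names(sort(d, decreasing = TRUE))[1:5])

  ## conflicts resolved toward the larger difference
  z <- matrix(1, 4, 30, dimnames = list(paste0("g", 1:4), paste0("c", 1:30)))
  clz <- setNames(rep(c("p", "A", "B"), each = 10), colnames(z))
  z["g1", clz == "A"] <- 5; z["g1", clz == "B"] <- 4   # shared, A wins
  z["g2", clz == "A"] <- 3
  z["g3", clz == "B"] <- 3
  z["g4", clz == "A"] <- 2; z["g4", clz == "B"] <- 2.5
  pz <- define_fate_markers(z, clz, list(A = "A", B = "B"), "p", 2)
  expect_true("g1" %in% pz$A$genes)
  expect_false("g1" %in% pz$B$genes)
  expect_setequal(pz$B$genes, c("g3", "g4"))
})

test_that("fate intensity is the mean marker fpm with strict input checks", {
  fx <- make_cluster_fixture()
  ones <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  expect_equal(unname(score_fate_intensity(ones, paste0("g", 1:5))),
               rep(1, 4))
  ## linear in uniform shifts
  i1 <- score_fate_intensity(fx$x, paste0("g", 1:20))
  i2 <- score_fate_intensity(fx$x + 0.5, paste0("g", 1:20))
  expect_equal(i2, i1 + 0.5)
  expect_error(score_fate_intensity(fx$x, c("g1", "nope")), "nope")

  ## committed cells separate from progenitors on the default sim
  pr <- default_processed()
  truth <- pr$sim$truth
  prog_ids <- names(truth$progenitor)[truth$progenitor]
  for (b in c("fate1", "fate2")) {
    genes <- intersect(truth$fate_programs[[b]]$gene, rownames(pr$expr))
    inten <- score_fate_intensity(pr$expr, genes)
    tips <- names(truth$cell_pseudotime)[truth$cell_branch == b &
                                         truth$cell_pseudotime > 0.8]
    tips <- intersect(tips, names(inten))
    prog <- intersect(prog_ids, names(inten))
    lab <- c(rep(TRUE, length(tips)), rep(FALSE, length(prog)))
    expect_gt(auroc(c(inten[tips], inten[prog]), lab), 0.95)
  }
})

test_that("activity calls use the progenitor mean + 2 sd rule", {
  set.seed(61)
  ref <- paste0("r", 1:2000)
  inten <- setNames(rnorm(5000), c(ref, paste0("q", 1:3000)))
  act <- call_active_program(inten, ref)
  ## null calibration: ~2.3% of a Gaussian exceeds mean + 2 sd
  frac <- mean(act[!names(inten) %in% ref])
  expect_gt(frac, 0.012); expect_lt(frac, 0.035)

  same <- setNames(rep(1, 50), paste0("c", 1:50))
  expect_warning(act0 <- call_active_program(same, names(same)), "zero")
  expect_false(any(act0))
  expect_error(call_active_program(inten[1:30], ref[1:10]), ">= 20")

  ## planted committed cells are called active
  pr <- default_processed()
  truth <- pr$sim$truth
  genes <- intersect(truth$fate_programs$fate1$gene, rownames(pr$expr))
  inten2 <- score_fate_intensity(pr$expr, genes)
  prog <- intersect(names(truth$progenitor)[truth$progenitor], names(inten2))
  act2 <- call_active_program(inten2, prog)
  committed <- intersect(names(truth$cell_pseudotime)[
    truth$cell_branch == "fate1" & truth$cell_pseudotime > 0.5], names(inten2))
  expect_gt(mean(act2[committed]), 0.9)
})

test_that("priming analysis quantifies exclusivity and co-activation", {
  ## mutually exclusive activation
  a <- matrix(FALSE, 300, 2, dimnames = list(NULL, c("A", "B")))
  a[1:50, 1] <- TRUE; a[51:100, 2] <- TRUE
  res <- priming_analysis(a)
  expect_equal(res$exclusivity, 1.0)
  expect_equal(res$pairs$both, 0)

  ## fully co-activated
  b <- matrix(FALSE, 100, 2); b[1:30, ] <- TRUE
  colnames(b) <- c("A", "B")
  expect_equal(priming_analysis(b)$exclusivity, 0)

  ## independent activation: co-active fraction ~ p * q
  set.seed(71)
  p <- 0.3; q <- 0.2; n <- 1000
  ind <- cbind(A = runif(n) < p, B = runif(n) < q)
  res2 <- priming_analysis(ind)
  co <- res2$pairs$both / n
  expect_lt(abs(co - p * q), 3 * sqrt(p * q * (1 - p * q) / n) + 0.01)
  expect_error(priming_analysis(a[, 1, drop = FALSE]), ">= 2")
})

test_that("mitotic projection averages cosine-nearest non-mitotic neighbours", {
  set.seed(81)
  coords <- matrix(rnorm(220 * 10), 220, 10,
                   dimnames = list(paste0("c", 1:220), NULL))
  mito <- c(rep(TRUE, 20), rep(FALSE, 200))
  emb <- matrix(rnorm(400), 200, 2,
                dimnames = list(paste0("c", 21:220), c("x", "y")))
  proj <- project_mitotic_cells(coords, mito, emb, k = 10)
  expect_equal(dim(proj$positions), c(20L, 2L))

  ## brute-force neighbour sets
  unit <- function(m) m / sqrt(rowSums(m^2))
  sim_all <- unit(coords[1:20, ]) %*% t(unit(coords[21:220, ]))
  for (i in c(1, 7, 20)) {
    nb <- rownames(coords)[20 + order(sim_all[i, ], decreasing = TRUE)[1:10]]
    expect_setequal(proj$neighbors[[i]], nb)
    ## position is the neighbour mean, hence inside their bounding box
    expect_equal(proj$positions[i, ], colMeans(emb[nb, ]), ignore_attr = TRUE)
    expect_true(all(proj$positions[i, ] >= apply(emb[nb, ], 2, min) - 1e-12))
    expect_true(all(proj$positions[i, ] <= apply(emb[nb, ], 2, max) + 1e-12))
  }

  ## identical cell with k = 1 lands exactly on its twin
  coords2 <- coords
  coords2[1, ] <- coords2[30, ]
  p1 <- project_mitotic_cells(coords2, mito, emb, k = 1)
  expect_equal(p1$positions[1, ], emb[rownames(coords2)[30], ],
               ignore_attr = TRUE)
  expect_error(project_mitotic_cells(coords, mito, emb, k = 300), "exceeds")
})

test_that("cell-cycle versus fate table flags a committed mitotic subset", {
  set.seed(91)
  n <- 1000
  cells <- paste0("c", 1:n)
  ## 5% of cells cycle AND run the fate program; progenitor reference first 400
  co <- sample(n, 50)
  cc <- setNames(rnorm(n), cells); cc[co] <- cc[co] + 5
  fate <- setNames(rnorm(n), cells); fate[co] <- fate[co] + 5
  res <- cellcycle_vs_fate(cc, fate, cells[1:400])
  frac <- res$n_co_active / n
  expect_gte(frac, 0.025); expect_lte(frac, 0.10)
  ## flags consistent with thresholds
  tab <- res$table
  expect_equal(tab$cc_active, tab$cc_score > res$thresholds["cc"],
               ignore_attr = TRUE)
  expect_equal(tab$fate_active, tab$fate_intensity > res$thresholds["fate"],
               ignore_attr = TRUE)
  ## no co-active cells when the programs never coincide
  cc2 <- cc; cc2[co] <- min(cc) - 1
  res2 <- cellcycle_vs_fate(cc2, fate, cells[1:400])
  expect_equal(length(intersect(res2$co_active, cells[co])), 0)
})
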