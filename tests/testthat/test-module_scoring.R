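test_that("two-group markers apply inclusive fold and strict p thresholds", {
  ## exact 3-fold gene on the linearized scale: fpm values chosen so
  ## (10^a - 1) / (10^b - 1) == 3 precisely
  a <- log10(1 + 3); b <- log10(1 + 1)
  x <- rbind(exact3 = c(rep(a, 10), rep(b, 10)),
             flat = rep(1, 20))
  colnames(x) <- paste0("c", 1:20)
  groups <- rep(c("g1", "g2"), each = 10)
  ## (the zero-variance epsilon guard caps the t reference at df = 1, so
  ## the p threshold here is looser than the study's 1e-10)
  got <- two_group_markers(x, groups, fold_min = 3, p_max = 1e-6)
  expect_true("exact3" %in% got)          # "at least three-fold" is inclusive
  expect_false("flat" %in% got)
  expect_false("exact3" %in% two_group_markers(x, groups, fold_min = 3 + 1e-9,
                                               p_max = 1e-6))
  tab <- attr(got, "table")
  expect_true(tab$zero_var[tab$gene == "exact3"])  # eps-guarded t statistic

  ## brute-force agreement on a random matrix
  set.seed(5)
  y <- matrix(rnorm(100 * 30, mean = 2, sd = 0.3), 100, 30,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:30)))
  y[1:10, 1:15] <- y[1:10, 1:15] + 1
  gr <- rep(c("hi", "lo"), each = 15)
  res <- two_group_markers(y, gr, fold_min = 2, p_max = 1e-3)
  lin <- pmax(10^y - 1, 0)
  bf <- vapply(rownames(y), function(g) {
    f <- mean(lin[g, 1:15]) / mean(lin[g, 16:30])
    p <- t.test(y[g, 1:15], y[g, 16:30])$p.value
    f >= 2 && p < 1e-3 && mean(y[g, 1:15]) > mean(y[g, 16:30])
  }, logical(1))
  expect_setequal(res, rownames(y)[bf])

  ## symmetry: the two directions never overlap, and every gene whose
  ## fpm and linearized means agree in direction is claimed by one side
  up <- two_group_markers(y, gr, fold_min = 1, p_max = 1)
  dn <- two_group_markers(y, factor(gr, levels = c("lo", "hi")),
                          fold_min = 1, p_max = 1)
  expect_length(intersect(up, dn), 0)
  lin <- pmax(10^y - 1, 0)
  agree_up <- rowMeans(y[, 1:15]) > rowMeans(y[, 16:30]) &
    rowMeans(lin[, 1:15]) >= rowMeans(lin[, 16:30])
  expect_true(all(rownames(y)[agree_up] %in% up))
  expect_true(all(rownames(y)[1:10] %in% up))
})

test_that("cross-dataset intersection records re-derivable criteria", {
  s1 <- structure(c("a", "b", "c"), criteria = list(fold_min = 3))
  s2 <- structure(c("b", "c", "d"), criteria = list(fold_min = 3))
  m <- intersect_across_datasets(list(s1, s2), name = "apical")
  expect_setequal(as.character(m), c("b", "c"))
  expect_length(attr(m, "criteria"), 2)
  expect_setequal(as.character(intersect_across_datasets(list(s1, s1))),
                  c("a", "b", "c"))
  expect_length(intersect_across_datasets(list(s1, structure("z"))), 0)

  ## audit property: re-running recorded criteria reproduces the set
  set.seed(6)
  y <- matrix(rnorm(60 * 40, 1, 0.2), 60, 40,
              dimnames = list(paste0("g", 1:60), paste0("c", 1:40)))
  y[1:8, 1:20] <- y[1:8, 1:20] + 1.5
  gr <- rep(c("A", "B"), each = 20)
  r1 <- two_group_markers(y, gr, 2, 1e-4)
  crit <- attr(r1, "criteria")
  r2 <- two_group_markers(y, gr, crit$fold_min, crit$p_max)
  expect_identical(as.character(r1), as.character(r2))
})

test_that("cluster enrichment keeps max/median outliers under ANOVA control", {
  set.seed(16)
  n <- 60
  x <- matrix(rnorm(40 * n, mean = 1, sd = 0.1), 40, n,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:n)))
  cl <- rep(paste0("k", 1:6), each = 10)
  x["g1", cl == "k1"] <- x["g1", cl == "k1"] + 3   # single-cluster gene
  tab <- cluster_enrichment_table(x, cl, fold_min = 4, p_max = 1e-10)
  expect_true("g1" %in% tab$gene)
  expect_equal(tab$cluster[tab$gene == "g1"], "k1")
  expect_false("g2" %in% tab$gene)                  # uniform gene excluded

  ## brute-force recomputation
  lin <- pmax(10^x - 1, 0)
  means <- sapply(unique(cl), function(k) rowMeans(lin[, cl == k]))
  ratio <- apply(means, 1, max) / apply(means, 1, median)
  pv <- apply(x, 1, function(y) oneway.test(y ~ cl, var.equal = TRUE)$p.value)
  keep <- ratio >= 4 & pv < 1e-10
  expect_setequal(tab$gene, rownames(x)[keep])
  expect_error(cluster_enrichment_table(x, rep("k", n)), ">= 2")
})

test_that("module scores average marker expression within clusters", {
  fxm <- matrix(c(1, 2, 3, 4), 1, 4,
                dimnames = list("m1", paste0("c", 1:4)))
  sc <- score_modules(fxm, rep("k1", 4), list(set = "m1"))
  expect_equal(unname(sc["k1", "set"]), 2.5)
  ## duplicated markers collapse to the same score
  sc2 <- score_modules(fxm, rep("k1", 4), list(set = c("m1", "m1")))
  expect_equal(sc, sc2)
  expect_error(score_modules(fxm, rep("k1", 4), list(set = "missing")),
               "no genes")

  ## the fate-matched cluster ranks first on its own marker module
  pr <- default_processed()
  truth <- pr$sim$truth
  cl <- ifelse(truth$progenitor[colnames(pr$expr)], "progenitor",
               truth$cell_branch[colnames(pr$expr)])
  sets <- lapply(truth$fate_programs, function(p)
    intersect(p$gene, rownames(pr$expr)))
  tab <- score_modules(pr$expr, cl, sets)
  for (b in names(sets)) expect_equal(rownames(tab)[which.max(tab[, b])], b)
})

test_that("similarity to a reference group behaves like mean latent correlation", {
  set.seed(26)
  lat <- matrix(rnorm(50 * 30), 50, 30,
                dimnames = list(paste0("c", 1:50), NULL))
  grp <- paste0("c", 1:10)
  sim <- similarity_to_group(lat, grp)
  ## brute-force double loop
  for (i in c(11, 25, 50)) {
    ref <- mean(sapply(grp, function(g) cor(lat[i, ], lat[g, ])))
    expect_equal(unname(sim[i]), ref, tolerance = 1e-12)
  }
  ## a cell identical to every group cell scores 1
  lat2 <- lat
  for (g in grp) lat2[g, ] <- lat2["c1", ]
  lat2["c20", ] <- lat2["c1", ]
  expect_equal(unname(similarity_to_group(lat2, grp)["c20"]), 1)
  ## orthogonal random vectors have near-zero similarity
  expect_lt(max(abs(sim[11:50])), 0.35)
  expect_lt(abs(mean(sim[11:50])), 0.1)
  ## constant latent vectors are flagged
  lat3 <- lat; lat3["c30", ] <- 1
  s3 <- similarity_to_group(lat3, grp)
  expect_true(is.na(s3["c30"]))
  expect_equal(attr(s3, "undefined"), "c30")
  expect_error(similarity_to_group(lat, "c1"), ">= 2")
})
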