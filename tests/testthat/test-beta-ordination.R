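test_that("Bray-Curtis matches direct arithmetic", {
  toy <- ct(c(1, 3, 2, 0), c("t1", "t2"), c("x", "y"))
  d <- bray_curtis(toy)
  expect_equal(d["x", "y"], (2 + 2) / (4 + 2))
  same <- ct(c(4, 4, 1, 1), c("t1", "t2"), c("x", "y"))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disjoint <- ct(c(5, 0, 0, 7), c("t1", "t2"), c("x", "y"))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  zero <- ct(c(5, 0, 1, 0), c("t1", "t2"), c("x", "y"))
  zero[, "y"] <- 0L
  expect_error(bray_curtis(zero), "all-zero sample.*y")
})

test_that("PCoA recovers geometry and fixes axis signs", {
  # two samples at distance d: one axis at +/- d/2
  m <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  p <- pcoa(m)
  expect_true(p$trivial)
  expect_equal(sort(unname(p$coordinates[, 1])), c(-0.3, 0.3))
  # three equidistant samples: two equal positive eigenvalues
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(m3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-9)
  expect_equal(p3$proportion_explained, c(0.5, 0.5), tolerance = 1e-9)
  # Euclidean distances round-trip through the embedding
  set.seed(4)
  pts <- matrix(rnorm(21), 7)
  de <- as.matrix(dist(pts)); dimnames(de) <- list(paste0("s", 1:7), paste0("s", 1:7))
  pe <- pcoa(de)
  expect_equal(unname(as.matrix(dist(pe$coordinates))), unname(de), tolerance = 1e-9)
  # sign convention: largest-magnitude loading on every axis is positive
  for (k in seq_len(ncol(pe$coordinates))) {
    expect_gt(pe$coordinates[which.max(abs(pe$coordinates[, k])), k], 0)
  }
})

test_that("PCoA agrees with an independent implementation", {
  sim <- generate_community(synth_config(n_signature = 10, n_shared = 20,
                                         depth_range = c(2000, 3000), seed = 12))
  d <- bray_curtis(sim$counts)
  mine <- pcoa(d)
  ref <- ape::pcoa(as.dist(d))
  npos <- ncol(mine$coordinates)
  expect_equal(mine$eigenvalues[1:npos], ref$values$Eigenvalues[1:npos],
               tolerance = 1e-8)
  expect_equal(abs(unname(mine$coordinates[, 1:2])),
               abs(unname(ref$vectors[, 1:2])), tolerance = 1e-6)
})

test_that("UPGMA agglomerates by average linkage with half-heights", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma(m)
  expect_equal(h$height, c(1, 4))
  expect_equal(h$merge[1, ], c(-2, -1)) # A and B first
  # ultrametricity: heights never decrease
  set.seed(5)
  for (i in 1:10) {
    pts <- matrix(rnorm(30), 10)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("s", 1:10), paste0("s", 1:10))
    hh <- upgma(dm)
    expect_true(all(diff(hh$height) >= -1e-12))
    # agrees with stats::hclust average linkage (tie-free input)
    expect_equal(hh$height, hclust(as.dist(dm), "average")$height / 2,
                 tolerance = 1e-12)
  }
  # all equal distances: every merge at the same height, deterministic order
  eq <- matrix(1, 4, 4) - diag(4)
  dimnames(eq) <- list(letters[1:4], letters[1:4])
  he <- upgma(eq)
  expect_equal(he$height, rep(0.5, 3))
  expect_equal(he$merge[1, ], c(-2, -1)) # lexicographic tie-break: a with b
})

test_that("UPGMA trees export as ultrametric Newick", {
  sim <- generate_community(synth_config(seed = 21))
  d <- bray_curtis(rarefy(sim$counts, seed = 1))
  tree <- upgma(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(d))
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
})

test_that("UPGMA separates the three habitats on synthetic data", {
  ari <- vapply(1:10, function(i) {
    sim <- generate_community(synth_config(seed = 400 + i))
    d <- bray_curtis(rarefy(sim$counts, seed = i))
    cl <- cutree(upgma(d), k = 3)
    hab <- sim$sample_info$habitat[match(names(cl), sim$sample_info$sample_id)]
    bf_ari(cl, hab)
  }, numeric(1))
  # the three-branch structure dominates; an occasional straggler sample may
  # cross branches at the default effect size
  expect_true(all(ari >= 0.8))
  expect_gte(sum(ari == 1), 5)
})

test_that("ANOSIM attains its extremes and matches vegan", {
  # complete separation: all between > all within -> R = 1
  d <- toy_dist(c(1, 1.2, 1.4, 10, 10.2, 10.4))
  lab <- rep(c("g1", "g2"), each = 3)
  expect_equal(anosim_test(d, lab, 99, seed = 1)$statistic, 1)
  # all distances tied -> R = 0
  eq <- matrix(1, 6, 6) - diag(6)
  dimnames(eq) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_equal(anosim_test(eq, lab, 99, seed = 1)$statistic, 0)
  # statistic equals vegan's on a real-shaped dataset
  sim <- generate_community(synth_config(seed = 31))
  db <- bray_curtis(rarefy(sim$counts, seed = 3))
  mine <- anosim_test(db, sim$sample_info$habitat, 99, seed = 1)
  ref <- vegan::anosim(as.dist(db), sim$sample_info$habitat, permutations = 9)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  # p floor
  expect_gte(mine$p_value, 1 / 100)
  # invariance under sample reordering
  perm <- sample(ncol(db))
  mine2 <- anosim_test(db[perm, perm], sim$sample_info$habitat[perm], 99, seed = 1)
  expect_equal(mine2$statistic, mine$statistic)
  expect_error(anosim_test(db[1:4, 1:4], c("a", "a", "a", "b")), "size 1")
})

test_that("Adonis partitions variance like vegan and handles degeneracy", {
  sim <- generate_community(synth_config(seed = 32))
  db <- bray_curtis(rarefy(sim$counts, seed = 3))
  lab <- sim$sample_info$habitat
  mine <- adonis_test(db, lab, 99, seed = 1)
  ref <- vegan::adonis2(as.dist(db) ~ g, data = data.frame(g = lab),
                        permutations = 9)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_gte(mine$r_squared, 0); expect_lte(mine$r_squared, 1)
  # unexplained share complements R^2 exactly
  ssw_share <- 1 - mine$r_squared
  expect_equal(mine$r_squared + ssw_share, 1, tolerance = 1e-12)
  # duplicated points within groups: SS_within = 0 -> R2 = 1, F = Inf
  pts <- c(0, 0, 5, 5)
  dd <- toy_dist(pts)
  deg <- adonis_test(dd, c("a", "a", "b", "b"), 19, seed = 1)
  expect_equal(deg$r_squared, 1)
  expect_true(is.infinite(deg$statistic))
  # reorder invariance
  perm <- sample(ncol(db))
  expect_equal(adonis_test(db[perm, perm], lab[perm], 99, seed = 1)$statistic,
               mine$statistic)
})

test_that("the published contrast table has one row per comparison", {
  sim <- generate_community(synth_config(seed = 33))
  d <- bray_curtis(rarefy(sim$counts, seed = 1))
  tab <- permutation_test_table(d, sim$sample_info, permutations = 99, seed = 5)
  expect_equal(nrow(tab), 4L)
  expect_match(tab$group[1], "water vs sediment vs intestine")
  expect_true(all(tab$permutations == 99))
  expect_true(all(tab$anosim_p >= 1 / 100 & tab$anosim_p <= 1))
  # rerun is identical under the same seed
  tab2 <- permutation_test_table(d, sim$sample_info, permutations = 99, seed = 5)
  expect_identical(tab, tab2)
})
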