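test_that("bipartite network applies the read filter and presence edges", {
  info <- six_group_info()
  m <- presence_table(list(
    everywhere = c("water", "sediment", "intestine"),
    gut_only = "intestine",
    pair = c("water", "sediment")
  ), info)
  m["everywhere", ] <- 2L # present in all six samples
  weak <- matrix(c(4L, 0L, 0L, 0L, 0L, 0L), 1,
                 dimnames = list("weak", info$sample_id))
  m <- rbind(m, weak)
  net <- build_bipartite(m, info, min_total_reads = 5)
  expect_false("weak" %in% net$genera$genus) # 4 reads: below the cutoff
  expect_equal(sum(net$edges$genus == "everywhere"), 6L) # all six groups
  # manual enumeration for the presence patterns
  gut_groups <- net$groups$group[net$groups$habitat == "intestine"]
  expect_setequal(net$edges$group[net$edges$genus == "gut_only"],
                  intersect(gut_groups, "MCc"))
  expect_setequal(net$edges$group[net$edges$genus == "pair"], c("MCw", "MCs"))
  expect_error(build_bipartite(weak, info, min_total_reads = 5), "no genus")
})

test_that("environment clusters follow the seven-way mapping", {
  info <- six_group_info()
  pattern <- list(
    g_int = "intestine", g_iw = c("intestine", "water"),
    g_all = c("intestine", "water", "sediment"),
    g_is = c("intestine", "sediment"), g_ws = c("water", "sediment"),
    g_w = "water", g_s = "sediment"
  )
  cl <- classify_env_clusters(build_bipartite(presence_table(pattern, info), info))
  got <- setNames(cl$assignment$cluster, cl$assignment$genus)
  expect_equal(got[c("g_int", "g_iw", "g_all", "g_is", "g_ws", "g_w", "g_s")],
               c(g_int = 1L, g_iw = 2L, g_all = 3L, g_is = 4L, g_ws = 5L,
                 g_w = 6L, g_s = 7L))
  expect_equal(sum(cl$breadth_summary$percent), 100, tolerance = 0.05)
  # all genera in all habitats -> 100% cluster 3
  allp <- presence_table(list(a = habitat_levels(), b = habitat_levels()), info)
  cl2 <- classify_env_clusters(build_bipartite(allp, info))
  expect_equal(cl2$breadth_summary$percent, c(0, 0, 100))
  # breadth percentages always close to 100 on random patterns
  set.seed(77)
  for (i in 1:10) {
    pat <- lapply(1:50, function(j) {
      sample(habitat_levels(), sample(1:3, 1))
    })
    names(pat) <- sprintf("g%02d", 1:50)
    cli <- classify_env_clusters(build_bipartite(presence_table(pat, info), info))
    expect_equal(sum(cli$breadth_summary$percent), 100, tolerance = 0.05)
  }
})

test_that("Spearman matrices use midranks and the t approximation", {
  rel <- rbind(up = (1:6) / 21, down = (6:1) / 21)
  colnames(rel) <- paste0("s", 1:6)
  sp <- spearman_matrix(rel)
  expect_equal(sp$rho["up", "down"], -1)
  expect_equal(sp$p["up", "down"], 0)
  rel2 <- rbind(a = c(1, 2, 2, 3), b = c(1, 3, 2, 4))
  colnames(rel2) <- paste0("s", 1:4)
  sp2 <- spearman_matrix(rel2)
  # brute-force midrank Spearman: Pearson correlation of the midranks
  bf <- cor(rank(c(1, 2, 2, 3)), rank(c(1, 3, 2, 4)))
  expect_equal(sp2$rho["a", "b"], bf)
  tstat <- bf * sqrt((4 - 2) / (1 - bf^2))
  expect_equal(sp2$p["a", "b"], 2 * pt(-abs(tstat), df = 2))
  # constant taxa are flagged and excluded
  rel3 <- rbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  colnames(rel3) <- paste0("s", 1:4)
  sp3 <- spearman_matrix(rel3)
  expect_equal(sp3$dropped, "flat")
  expect_true(is.na(sp3$rho["a", "flat"]))
})

test_that("edge filtering is inclusive on rho, strict on alpha", {
  rho <- matrix(c(1, 0.75, 0.80, 0.75, 1, -0.9, 0.80, -0.9, 1), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(c(0, 0.04, 0.06, 0.04, 0, 0.01, 0.06, 0.01, 0), 3,
              dimnames = dimnames(rho))
  e <- filter_edges(rho, p)
  expect_equal(nrow(e), 1L) # only a-b: rho = 0.75 (inclusive), p = 0.04
  expect_equal(e$source, "a"); expect_equal(e$target, "b")
  # absolute mode admits strong negative correlations
  e_abs <- filter_edges(rho, p, mode = "absolute")
  expect_setequal(paste(e_abs$source, e_abs$target), c("a b", "b c"))
  # monotonicity: relaxing alpha never removes edges
  e_loose <- filter_edges(rho, p, alpha = 0.10)
  expect_true(all(paste(e$source, e$target) %in%
                    paste(e_loose$source, e_loose$target)))
  # six-taxon toy equals a manual filter
  set.seed(3)
  rel <- matrix(runif(60), 6, 10, dimnames = list(letters[1:6], paste0("s", 1:10)))
  sp <- spearman_matrix(rel)
  e2 <- filter_edges(sp$rho, sp$p, rho_min = 0.3, alpha = 0.2)
  manual <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    if (sp$rho[i, j] >= 0.3 && sp$p[i, j] < 0.2) manual <- manual + 1
  }
  expect_equal(nrow(e2), manual)
})

test_that("graph metrics match closed forms on canonical graphs", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  nt <- graph_metrics(tri)
  expect_equal(nt$globals$transitivity, 1)
  expect_equal(nt$nodes$clustering, rep(1, 3))
  expect_equal(nt$nodes$betweenness, rep(0, 3))
  expect_equal(nt$globals$diameter, 1)

  path <- igraph::graph_from_literal(A - B - C)
  np <- graph_metrics(path)
  expect_equal(np$nodes$betweenness[np$nodes$genus == "B"], 1)
  expect_equal(np$globals$transitivity, 0)
  expect_equal(np$globals$diameter, 2)
  expect_equal(np$globals$avg_path_length, 4 / 3)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  ns <- graph_metrics(star)
  expect_equal(ns$nodes$betweenness[ns$nodes$genus == "hub"], choose(4, 2))
})

test_that("graph metrics equal the brute-force oracle on random graphs", {
  set.seed(23)
  for (i in 1:30) {
    g <- igraph::sample_gnp(12, runif(1, 0.1, 0.5))
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("n%02d", 1:12)
    expect_graph_metrics_match(g, label = paste("random graph", i))
  }
})

test_that("module detection maximises modularity sensibly", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  net <- detect_modules(k5, seed = 1)
  expect_equal(length(unique(net$partition)), 1L)
  expect_equal(net$globals$modularity, 0)
  # Q never below the all-singletons partition
  set.seed(11)
  for (i in 1:10) {
    g <- igraph::sample_gnp(15, 0.2)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("n%02d", 1:15)
    net <- detect_modules(g, seed = i)
    q_singletons <- igraph::modularity(g, seq_len(igraph::vcount(g)))
    expect_gte(net$globals$modularity, q_singletons - 1e-12)
  }
  expect_error(detect_modules(igraph::make_empty_graph(3, directed = FALSE)),
               "at least one edge")
})

test_that("environment labels follow abundance with a deterministic tie-break", {
  info <- six_group_info()
  m <- rbind(
    sed = c(0L, 0L, 30L, 30L, 0L, 0L),
    uni = c(10L, 10L, 10L, 10L, 10L, 10L),
    aqua = c(40L, 40L, 0L, 0L, 5L, 5L)
  )
  colnames(m) <- info$sample_id
  g <- igraph::graph_from_literal(sed - uni - aqua)
  net <- assign_environment_labels(g, m, info)
  labels <- setNames(net$nodes$env, net$nodes$genus)
  expect_equal(labels[["sed"]], "sediment")
  expect_equal(labels[["aqua"]], "water")
  expect_false(any(net$nodes$env_tie))
  # identical composition everywhere: exact tie -> water by the stated order
  tiem <- rbind(u1 = rep(10L, 6), u2 = rep(10L, 6))
  colnames(tiem) <- info$sample_id
  tnet <- assign_environment_labels(igraph::graph_from_literal(u1 - u2), tiem, info)
  expect_equal(unique(tnet$nodes$env), "water")
  expect_true(all(tnet$nodes$env_tie))
})

test_that("synthetic signature taxa are labelled with their home habitat", {
  hits <- 0; total <- 0
  for (i in 1:20) {
    sim <- generate_community(synth_config(seed = 500 + i))
    sig <- sim$truth$signature_habitat
    sig_taxa <- names(sig)[sig != "shared"]
    g <- igraph::make_ring(length(sig_taxa))
    igraph::V(g)$name <- sig_taxa
    net <- assign_environment_labels(g, sim$counts, sim$sample_info)
    hits <- hits + sum(net$nodes$env == sig[net$nodes$genus])
    total <- total + length(sig_taxa)
  }
  expect_gte(hits / total, 0.95)
})

test_that("hub ranking orders by betweenness with stated tie-breaks", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  hubs <- hub_ranking(graph_metrics(star), k = 2)
  expect_equal(hubs$genus[1], "hub")
  expect_equal(hubs$betweenness[1], 6)
  expect_equal(nrow(hubs), 2L)
  # all-isomorphic cycle: ordering falls back to names, deterministically
  cyc <- igraph::make_ring(5)
  igraph::V(cyc)$name <- c("e", "c", "a", "d", "b")
  hubs_c <- hub_ranking(graph_metrics(cyc), k = 5)
  expect_equal(hubs_c$genus, c("a", "b", "c", "d", "e"))
  # k above the node count returns the full list
  expect_equal(nrow(hub_ranking(graph_metrics(cyc), k = 99)), 5L)
  # a filter that keeps nothing yields an empty network and empty ranking
  rho <- diag(2); dimnames(rho) <- list(c("a", "b"), c("a", "b"))
  p <- rho * 0
  empty <- filter_edges(rho, p, rho_min = 0.9)
  expect_equal(nrow(empty), 0L)
})

test_that("edge degrees are consistent and recovery meets the planted truth", {
  # degree sum identity on a synthetic network
  sim <- generate_community(synth_config(n_replicates = 5, seed = 600))
  net <- graph_metrics(build_conet(sim$counts))
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  # recovery regime: 30 samples, latent rho 0.95, no pre-filter truncation
  sens <- prec <- numeric(20)
  for (i in 1:20) {
    sim <- generate_community(synth_config(n_replicates = 5, module_rho = 0.95,
                                           seed = 700 + i))
    net <- build_conet(sim$counts, top_n = nrow(sim$counts))
    planted <- planted_edge_set(sim$truth, 0.75)
    pk <- paste(pmin(planted$a, planted$b), pmax(planted$a, planted$b))
    dk <- paste(pmin(net$edges$source, net$edges$target),
                pmax(net$edges$source, net$edges$target))
    sens[i] <- mean(pk %in% dk)
    prec[i] <- mean(dk %in% pk)
  }
  expect_true(all(sens >= 0.8))
  expect_true(all(prec >= 0.9))
})

test_that("network export writes edge, node, global and GraphML files", {
  sim <- generate_community(synth_config(seed = 601))
  net <- detect_modules(graph_metrics(build_conet(sim$counts)), seed = 1)
  out <- withr::local_tempdir()
  write_conet(net, out)
  expect_true(all(file.exists(file.path(out, c("conet_edges.tsv",
                                               "conet_nodes.tsv",
                                               "conet_globals.tsv",
                                               "conet.graphml")))))
  g2 <- igraph::read_graph(file.path(out, "conet.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), nrow(net$edges))
})
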