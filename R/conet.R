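# Spearman co-correlation network: edge filtering, topology metrics,
# community detection and betweenness hubs.

#' Spearman correlation and p-value matrices between taxa
#'
#' Midrank-based Spearman rho (Pearson correlation of midranks, exact under
#' ties) for every taxon pair, computed across samples on relative
#' abundances. Two-sided p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' with `p = 0` when `rho = +/-1`. Constant (zero-variance) taxa yield `NA`
#' correlations; such pairs are flagged by the `dropped` element and are
#' never turned into edges.
#'
#' @param rel relative-abundance matrix, taxa x samples.
#' @param taxa optional subset of taxon ids (rows) to correlate.
#' @return list with `rho`, `p` (taxa x taxa matrices), `n` (samples), and
#'   `dropped` (constant taxa).
#' @export
spearman_matrix <- function(rel, taxa = NULL) {
  rel <- as.matrix(rel)
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, rownames(rel))
    if (length(miss)) stop("taxa not in table: ", paste(utils::head(miss, 5),
                                                        collapse = ", "), call. = FALSE)
    rel <- rel[taxa, , drop = FALSE]
  }
  n <- ncol(rel)
  if (n < 4) stop("need at least 4 samples for correlation p-values", call. = FALSE)
  if (nrow(rel) < 2) stop("need at least two taxa", call. = FALSE)
  constant <- apply(rel, 1, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(t(rel), method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p, n = n, dropped = rownames(rel)[constant])
}

#' Filter correlation edges by strength and significance
#'
#' Retains taxon pairs with `rho >= rho_min` (or `|rho| >= rho_min` with
#' `mode = "absolute"`) and `p < alpha`; the threshold is inclusive. `NA`
#' correlations (constant taxa) are excluded. Optionally applies a
#' Benjamini--Hochberg correction across all tested pairs before filtering.
#'
#' @param rho,p square matrices from [spearman_matrix()].
#' @param rho_min correlation threshold (default 0.75).
#' @param alpha significance level on the (possibly adjusted) p (default 0.05).
#' @param mode `"positive"` keeps only positive correlations (the default
#'   reading of the rho >= 0.75 rule); `"absolute"` keeps both signs.
#' @param adjust_p apply Benjamini--Hochberg across pairs first.
#' @return data frame `source`, `target`, `rho`, `p` (one row per unordered
#'   pair, source < target).
#' @export
filter_edges <- function(rho, p, rho_min = 0.75, alpha = 0.05,
                         mode = c("positive", "absolute"), adjust_p = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(dim(rho) == dim(p)))
  ut <- upper.tri(rho)
  idx <- which(ut, arr.ind = TRUE)
  rv <- rho[ut]
  pv <- p[ut]
  if (adjust_p) pv <- stats::p.adjust(pv, method = "BH")
  strength <- if (mode == "positive") rv else abs(rv)
  keep <- !is.na(rv) & strength >= rho_min & pv < alpha
  data.frame(source = rownames(rho)[idx[keep, 1]],
             target = colnames(rho)[idx[keep, 2]],
             rho = rv[keep], p = pv[keep], stringsAsFactors = FALSE)
}

conet_from_edges <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, edges = edges,
                 nodes = data.frame(genus = igraph::V(g)$name,
                                    stringsAsFactors = FALSE),
                 globals = list(), partition = NULL),
            class = "conet")
}

as_conet <- function(x) {
  if (inherits(x, "conet")) return(x)
  if (inherits(x, "igraph")) {
    if (is.null(igraph::V(x)$name)) {
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    }
    el <- igraph::as_data_frame(x, what = "edges")
    return(structure(list(graph = x,
                          edges = data.frame(source = el$from, target = el$to,
                                             stringsAsFactors = FALSE),
                          nodes = data.frame(genus = igraph::V(x)$name,
                                             stringsAsFactors = FALSE),
                          globals = list(), partition = NULL),
                     class = "conet"))
  }
  stop("cannot interpret object as a co-correlation network", call. = FALSE)
}

#' Build the thresholded Spearman co-correlation network
#'
#' Applies the node pre-filter (top `top_n` taxa by total abundance that are
#' present in at least `min_prevalence` samples), computes the Spearman
#' matrices on relative abundances, filters edges, and assembles the graph.
#' Isolated taxa (no surviving edge) are not nodes.
#'
#' @param table count table (typically genus-level, rarefied).
#' @param top_n size of the abundance pre-filter (default 100).
#' @param min_prevalence minimum number of samples a taxon must occur in.
#' @param rho_min,alpha,mode,adjust_p passed to [filter_edges()].
#' @return object of class `conet` (graph, edges, nodes, globals, partition).
#' @export
build_conet <- function(table, top_n = 100, min_prevalence = 4,
                        rho_min = 0.75, alpha = 0.05,
                        mode = c("positive", "absolute"), adjust_p = FALSE) {
  x <- as_count_table(table)
  keep <- top_n_taxa(x, min(top_n, nrow(x)))
  keep <- keep[rowSums(x[keep, , drop = FALSE] > 0) >= min_prevalence]
  if (length(keep) < 2) stop("fewer than two taxa survive the pre-filter", call. = FALSE)
  rel <- relative_abundance(x)
  sp <- spearman_matrix(rel, taxa = keep)
  edges <- filter_edges(sp$rho, sp$p, rho_min = rho_min, alpha = alpha,
                        mode = mode, adjust_p = adjust_p)
  net <- conet_from_edges(edges)
  net$prefilter <- keep
  net
}

#' Fill in node-level and global topology metrics
#'
#' Node metrics: degree, local clustering coefficient (0 for degree < 2),
#' betweenness centrality (Brandes, unnormalised, endpoints excluded).
#' Globals: node and edge counts, mean local clustering, transitivity
#' (3 triangles / connected triples), and diameter plus average shortest
#' path length over the largest connected component (unweighted).
#'
#' @param net a `conet` (or an igraph graph).
#' @return the `conet` with `nodes` columns `degree`, `clustering`,
#'   `betweenness` and a populated `globals` list.
#' @export
graph_metrics <- function(net) {
  net <- as_conet(net)
  g <- net$graph
  nv <- igraph::vcount(g)
  deg <- igraph::degree(g)
  loc <- igraph::transitivity(g, type = "local", vids = igraph::V(g))
  loc[!is.finite(loc)] <- 0
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  trans <- igraph::transitivity(g, type = "global")
  if (!is.finite(trans)) trans <- 0
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  net$nodes <- data.frame(genus = igraph::V(g)$name, degree = deg,
                          clustering = loc, betweenness = btw,
                          row.names = NULL, stringsAsFactors = FALSE)
  net$globals <- list(
    n_nodes = nv,
    n_edges = igraph::ecount(g),
    avg_clustering = mean(loc),
    transitivity = trans,
    diameter = if (igraph::vcount(giant) > 1) {
      igraph::diameter(giant, directed = FALSE, unconnected = FALSE)
    } else 0,
    avg_path_length = if (igraph::vcount(giant) > 1) {
      igraph::mean_distance(giant, directed = FALSE)
    } else 0
  )
  net
}

#' Louvain community detection with the modularity of the partition
#'
#' Seeded greedy multilevel (Louvain) optimisation; the reported Q is the
#' standard Newman--Girvan modularity of the returned partition
#' (`sum_c (e_c/m - (d_c/2m)^2)`), regardless of the resolution used to find
#' it.
#'
#' @param net a `conet` (or igraph graph) with at least one edge.
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed integer seed fixing the (stochastic) optimisation.
#' @return the `conet` with `partition` (named module ids) and
#'   `globals$modularity` set.
#' @export
detect_modules <- function(net, resolution = 1.0, seed = NULL) {
  net <- as_conet(net)
  g <- net$graph
  if (igraph::ecount(g) < 1) stop("community detection needs at least one edge",
                                  call. = FALSE)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  net$partition <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  net$globals$modularity <- igraph::modularity(g, memb)
  net$nodes$module <- net$partition[net$nodes$genus]
  net
}

#' Label network nodes and modules with their dominant habitat
#'
#' Each node gets the habitat in which its mean relative abundance is
#' maximal; ties are broken deterministically in the order water < sediment
#' < intestine and flagged. Modules (if detected) are labelled by majority
#' vote of their member nodes, with the same tie-break.
#'
#' @param net a `conet`.
#' @param table count table containing the node taxa.
#' @param info sample metadata.
#' @return the `conet` with node columns `env`, `env_tie` and (when a
#'   partition exists) `module_env`.
#' @export
assign_environment_labels <- function(net, table, info) {
  net <- as_conet(net)
  x <- as_count_table(table)
  info <- validate_sample_info(info, x)
  info <- info[match(colnames(x), info$sample_id), ]
  miss <- setdiff(net$nodes$genus, rownames(x))
  if (length(miss)) stop("network taxa absent from table: ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  rel <- relative_abundance(x)
  habs <- intersect(habitat_levels(), unique(info$habitat))
  mean_by_hab <- vapply(habs, function(h) {
    rowMeans(rel[net$nodes$genus, info$habitat == h, drop = FALSE])
  }, numeric(nrow(net$nodes)))
  if (!is.matrix(mean_by_hab)) mean_by_hab <- matrix(mean_by_hab, nrow = 1L,
                                                     dimnames = list(NULL, habs))
  top <- apply(mean_by_hab, 1, max)
  net$nodes$env <- habs[apply(mean_by_hab, 1, which.max)]
  net$nodes$env_tie <- rowSums(mean_by_hab >= top - 1e-15) > 1
  if (!is.null(net$partition)) {
    net$nodes$module_env <- vapply(net$nodes$module, function(m) {
      votes <- table(factor(net$nodes$env[net$nodes$module == m], levels = habs))
      habs[which.max(votes)]
    }, character(1))
  }
  net
}

#' Hub ranking by betweenness centrality
#'
#' Nodes sorted by betweenness (descending), ties broken by degree then by
#' name, reported with their (degree, clustering, betweenness) triplets.
#'
#' @param net a `conet` with metrics computed (see [graph_metrics()]).
#' @param k number of hubs to return; capped at the node count.
#' @return data frame of the top `k` nodes.
#' @export
hub_ranking <- function(net, k = 6) {
  net <- as_conet(net)
  if (is.null(net$nodes$betweenness)) net <- graph_metrics(net)
  nd <- net$nodes
  if (nrow(nd) == 0) return(nd)
  ord <- order(-nd$betweenness, -nd$degree, nd$genus)
  utils::head(nd[ord, , drop = FALSE], min(k, nrow(nd)))
}

#' Write network tables and GraphML
#'
#' Writes the edge list (`source`, `target`, `rho`, `p`), the node attribute
#' table, the global metrics and a GraphML export.
#'
#' @param net a `conet`.
#' @param outdir output directory, created if missing.
#' @param prefix file-name prefix.
#' @return `outdir`, invisibly.
#' @export
write_conet <- function(net, outdir, prefix = "conet") {
  net <- as_conet(net)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(net$edges, file.path(outdir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, file.path(outdir, paste0(prefix, "_nodes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(net$globals)) {
    gl <- data.frame(metric = names(net$globals),
                     value = unlist(net$globals, use.names = FALSE))
    utils::write.table(gl, file.path(outdir, paste0(prefix, "_globals.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  igraph::write_graph(net$graph, file.path(outdir, paste0(prefix, ".graphml")),
                      format = "graphml")
  invisible(outdir)
}
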