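# End-to-end orchestration: simulate (or read) -> rarefy -> alpha -> beta ->
# composition -> bipartite -> co-correlation network, with one master seed
# deriving every stage seed and all stage outputs written as TSV.

#' Pipeline run configuration
#'
#' Either the three input paths (`otu_table`, `taxonomy`, `sample_info`) or a
#' [synth_config()] must be supplied. One master seed drives every
#' stochastic stage through [stage_seed()].
#'
#' @param otu_table,taxonomy,sample_info input TSV paths, or `NULL` to
#'   simulate.
#' @param synth a [synth_config()] used when no input paths are given.
#' @param depth rarefaction depth policy (`"min"` or a count).
#' @param alpha_test between-group test for alpha diversity (`"t"`,
#'   `"anova"` or `"kruskal"`); the default follows the pairwise-t
#'   convention of the study design.
#' @param permutations permutations for ANOSIM/Adonis.
#' @param rho_min,alpha,mode network edge thresholds.
#' @param min_total_reads bipartite genus filter.
#' @param top_n,min_prevalence co-correlation node pre-filter.
#' @param others_threshold composition "others" binning threshold.
#' @param hub_k hubs reported.
#' @param seed master seed.
#' @param outdir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(otu_table = NULL, taxonomy = NULL, sample_info = NULL,
                       synth = synth_config(), depth = "min",
                       alpha_test = "t", permutations = 999,
                       rho_min = 0.75, alpha = 0.05, mode = "positive",
                       min_total_reads = 5, top_n = 100, min_prevalence = 4,
                       others_threshold = 0.01, hub_k = 6,
                       seed = 1L, outdir = tempfile("miconet_run_")) {
  paths <- list(otu_table = otu_table, taxonomy = taxonomy, sample_info = sample_info)
  given <- !vapply(paths, is.null, logical(1))
  if (any(given) && !all(given)) {
    stop("supply all three of otu_table, taxonomy and sample_info, or none",
         call. = FALSE)
  }
  structure(list(paths = paths, simulate = !any(given), synth = synth,
                 depth = depth, alpha_test = alpha_test,
                 permutations = permutations, rho_min = rho_min, alpha = alpha,
                 mode = mode, min_total_reads = min_total_reads, top_n = top_n,
                 min_prevalence = min_prevalence,
                 others_threshold = others_threshold, hub_k = hub_k,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage, writes all stage outputs under `config$outdir`, and
#' returns a report whose percentages are re-derived from its own counts as
#' an internal consistency check. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # --- input stage -----------------------------------------------------
  if (config$simulate) {
    synth <- config$synth
    synth$seed <- stage_seed(config$seed, "simulate")
    sim <- generate_community(synth)
    counts <- sim$counts; tax <- sim$taxonomy; info <- sim$sample_info
    write_community(sim, file.path(out, "simulated"))
    note("simulate: %d taxa x %d samples", nrow(counts), ncol(counts))
  } else {
    for (p in unlist(config$paths)) {
      if (!file.exists(p)) stop("input stage: missing file ", p, call. = FALSE)
    }
    counts <- read_count_table(config$paths$otu_table)
    tax <- read_taxonomy(config$paths$taxonomy)
    info <- read_sample_info(config$paths$sample_info)
    sim <- NULL
    note("input: %d taxa x %d samples read", nrow(counts), ncol(counts))
  }
  info <- validate_sample_info(info, counts)

  # --- rarefaction ------------------------------------------------------
  rare <- rarefy(counts, depth = config$depth,
                 seed = stage_seed(config$seed, "rarefy"))
  write_count_table(rare, file.path(out, "otu_table_rarefied.tsv"))
  note("rarefy: depth %d", sum(rare[, 1]))

  # --- alpha diversity --------------------------------------------------
  adiv <- alpha_diversity(rare)
  write_tsv(adiv, file.path(out, "alpha_diversity.tsv"))
  measures <- c("chao1", "ace", "shannon", "simpson")
  idx <- match(adiv$sample_id, info$sample_id)
  alpha_tests <- do.call(rbind, lapply(measures, function(ms) {
    habs <- intersect(habitat_levels(), unique(info$habitat))
    pairs <- utils::combn(habs, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(pr) {
      sel <- info$habitat[idx] %in% pr
      gt <- group_test(adiv[[ms]][sel], info$habitat[idx][sel],
                       test = config$alpha_test)
      cbind(measure = ms, gt)
    }))
  }))
  write_tsv(alpha_tests, file.path(out, "alpha_group_tests.tsv"))
  note("alpha: %d samples, %d pairwise tests", nrow(adiv), nrow(alpha_tests))

  # --- beta diversity ---------------------------------------------------
  d <- bray_curtis(rare)
  write_tsv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
            file.path(out, "bray_curtis.tsv"))
  ord <- pcoa(d)
  write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            file.path(out, "pcoa_coordinates.tsv"))
  tree <- upgma(d)
  write_dendrogram_newick(tree, file.path(out, "upgma.nwk"))
  perm <- permutation_test_table(d, info, permutations = config$permutations,
                                 seed = stage_seed(config$seed, "permtests"))
  write_tsv(perm, file.path(out, "permutation_tests.tsv"))
  note("beta: PC1 %.2f%%, PC2 %.2f%% of positive-eigenvalue variation",
       100 * ord$proportion_explained[1], 100 * ord$proportion_explained[2])

  # --- composition ------------------------------------------------------
  phylum <- aggregate_rank(rare, tax, "phylum")
  rel_ph <- bin_others(relative_abundance(phylum),
                       threshold = config$others_threshold)
  write_tsv(data.frame(phylum = rownames(rel_ph), rel_ph, check.names = FALSE),
            file.path(out, "phylum_composition.tsv"))
  genus <- aggregate_rank(rare, tax, "genus")
  heat <- log10_heatmap_matrix(genus, n = 40)
  write_tsv(data.frame(genus = rownames(heat), heat, check.names = FALSE),
            file.path(out, "genus_top40_log10.tsv"))
  note("composition: %d phyla (%d after binning), %d genera",
       nrow(phylum), nrow(rel_ph), nrow(genus))

  # --- bipartite network ------------------------------------------------
  bip <- build_bipartite(genus, info, min_total_reads = config$min_total_reads)
  clusters <- classify_env_clusters(bip)
  write_tsv(clusters$assignment, file.path(out, "bipartite_clusters.tsv"))
  write_tsv(clusters$breadth_summary, file.path(out, "bipartite_breadth.tsv"))
  write_tsv(clusters$sharing, file.path(out, "bipartite_sharing.tsv"))
  # internal consistency: percentages must re-derive from their own counts
  stopifnot(identical(clusters$breadth_summary$percent,
                      pct(clusters$breadth_summary$n_genera, clusters$n_genera)))
  stopifnot(abs(sum(clusters$breadth_summary$percent) - 100) < 0.05)
  note("bipartite: %d genus nodes", clusters$n_genera)

  # --- co-correlation network ------------------------------------------
  net <- build_conet(genus, top_n = config$top_n,
                     min_prevalence = config$min_prevalence,
                     rho_min = config$rho_min, alpha = config$alpha,
                     mode = config$mode)
  net <- graph_metrics(net)
  net <- detect_modules(net, seed = stage_seed(config$seed, "louvain"))
  net <- assign_environment_labels(net, genus, info)
  write_conet(net, out)
  note("conet: %d nodes, %d edges, Q = %.3f", net$globals$n_nodes,
       net$globals$n_edges, net$globals$modularity)

  hubs <- hub_ranking(net, k = config$hub_k)
  write_tsv(hubs, file.path(out, "conet_hubs.tsv"))

  report <- structure(list(
    parameters = config,
    alpha = adiv,
    alpha_tests = alpha_tests,
    ordination = ord,
    permutation_tests = perm,
    cluster_summary = clusters,
    network_globals = net$globals,
    hubs = hubs,
    network = net,
    truth = if (!is.null(sim)) sim$truth else NULL,
    log = log_lines
  ), class = "run_report")
  writeLines(log_lines, file.path(out, "run_log.txt"))
  report
}
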