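# Bipartite genus-environment association network and the seven-way
# environment-sharing classification.

#' Build the bipartite genus--group association network
#'
#' Source nodes are the sample groups (mode x habitat, six in the full
#' design), target nodes are genera. A genus is retained when its total read
#' count reaches `min_total_reads`; an edge links a genus to a group when the
#' genus has at least one read in at least one sample of that group.
#'
#' @param table genus-level count table.
#' @param info sample metadata.
#' @param min_total_reads minimum total reads for a genus node (default 5).
#' @return list of class `bipartite_net`: `genera` (data frame with totals),
#'   `groups` (data frame with group, habitat, mode), `edges` (genus, group).
#' @export
build_bipartite <- function(table, info, min_total_reads = 5) {
  x <- as_count_table(table)
  info <- validate_sample_info(info, x)
  info <- info[match(colnames(x), info$sample_id), ]
  keep <- rowSums(x) >= min_total_reads
  if (!any(keep)) {
    stop("no genus reaches ", min_total_reads, " total reads", call. = FALSE)
  }
  x <- x[keep, , drop = FALSE]
  grp_key <- paste0(info$mode, habitat_code(info$habitat))
  groups <- unique(data.frame(group = grp_key, habitat = info$habitat,
                              mode = info$mode, stringsAsFactors = FALSE))
  present <- vapply(groups$group, function(g) {
    rowSums(x[, grp_key == g, drop = FALSE]) > 0
  }, logical(nrow(x)))
  if (!is.matrix(present)) present <- matrix(present, nrow = 1L)
  edges <- which(present, arr.ind = TRUE)
  structure(list(
    genera = data.frame(genus = rownames(x), total = rowSums(x),
                        row.names = NULL, stringsAsFactors = FALSE),
    groups = groups,
    edges = data.frame(genus = rownames(x)[edges[, 1]],
                       group = groups$group[edges[, 2]],
                       stringsAsFactors = FALSE)
  ), class = "bipartite_net")
}

# Fixed seven-way numbering of environment sets (MC/RC collapsed):
# 1 intestine only, 2 intestine+water, 3 all three, 4 intestine+sediment,
# 5 water+sediment, 6 water only, 7 sediment only.
env_cluster_id <- function(env_sets) {
  vapply(env_sets, function(s) {
    key <- paste(sort(s), collapse = "+")
    switch(key,
      "intestine" = 1L,
      "intestine+water" = 2L,
      "intestine+sediment+water" = 3L,
      "intestine+sediment" = 4L,
      "sediment+water" = 5L,
      "water" = 6L,
      "sediment" = 7L,
      stop("unexpected environment set: ", key, call. = FALSE)
    )
  }, integer(1))
}

#' Classify genera by the set of environments they associate with
#'
#' Collapses the bipartite network's group nodes to their habitats and
#' assigns each genus one of seven clusters (1 intestine-only, 2
#' intestine+water, 3 all three, 4 intestine+sediment, 5 water+sediment,
#' 6 water-only, 7 sediment-only). Returns the assignment plus summary
#' percentages (two decimals): the share of genera associated with one, two
#' and all three environments, and the sharing profile of each habitat's
#' genus set (unique to it, shared with each other habitat, shared by all).
#'
#' @param net a [build_bipartite()] result.
#' @return list of class `env_clusters`: `assignment` (genus, cluster,
#'   environments), `n_genera`, `breadth_summary` (data frame), and
#'   `sharing` (per-habitat data frame).
#' @export
classify_env_clusters <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  hab_of <- net$groups$habitat[match(net$edges$group, net$groups$group)]
  env_sets <- split(hab_of, net$edges$genus)
  env_sets <- lapply(env_sets, unique)
  genera <- names(env_sets)
  cluster <- env_cluster_id(env_sets)
  n <- length(genera)

  breadth <- vapply(env_sets, length, integer(1))
  breadth_summary <- data.frame(
    environments = c("one", "two", "three"),
    clusters = c("1,6,7", "2,4,5", "3"),
    n_genera = c(sum(breadth == 1), sum(breadth == 2), sum(breadth == 3)),
    stringsAsFactors = FALSE
  )
  breadth_summary$percent <- pct(breadth_summary$n_genera, n)

  sharing <- do.call(rbind, lapply(habitat_levels(), function(h) {
    in_h <- vapply(env_sets, function(s) h %in% s, logical(1))
    n_h <- sum(in_h)
    if (n_h == 0) return(NULL)
    others <- setdiff(habitat_levels(), h)
    unique_h <- sum(in_h & breadth == 1)
    shared_all <- sum(in_h & breadth == 3)
    rows <- data.frame(
      habitat = h,
      pattern = c("unique", paste0("shared_with_", others), "shared_all"),
      n_genera = c(unique_h,
                   vapply(others, function(o) {
                     sum(in_h & vapply(env_sets, function(s) o %in% s, logical(1)))
                   }, numeric(1)),
                   shared_all),
      stringsAsFactors = FALSE
    )
    rows$percent <- pct(rows$n_genera, n_h)
    rows$n_habitat_genera <- n_h
    rows
  }))
  rownames(sharing) <- NULL

  structure(list(
    assignment = data.frame(genus = genera, cluster = cluster,
                            environments = vapply(env_sets, function(s) {
                              paste(sort(s), collapse = "+")
                            }, character(1)),
                            row.names = NULL, stringsAsFactors = FALSE),
    n_genera = n,
    breadth_summary = breadth_summary,
    sharing = sharing
  ), class = "env_clusters")
}
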