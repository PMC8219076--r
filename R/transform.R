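# Depth normalisation, rank aggregation and composition summaries.

#' Rarefy a count table to a common depth
#'
#' Random subsampling without replacement (multivariate hypergeometric) of
#' each sample's reads down to `depth`, the standard reading of "normalised
#' to the least sequence number". Sampling is delegated to
#' [vegan::rrarefy()]; a fixed `seed` makes the draw reproducible.
#'
#' @param table count table, taxa x samples.
#' @param depth target depth, or `"min"` for the smallest library size.
#' @param seed integer seed or `NULL`.
#' @return rarefied integer count table; every column sums to `depth`.
#' @export
rarefy <- function(table, depth = "min", seed = NULL) {
  x <- as_count_table(table)
  cs <- colSums(x)
  if (identical(depth, "min")) depth <- min(cs)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("`depth` must be \"min\" or a positive count", call. = FALSE)
  }
  depth <- as.integer(round(depth))
  low <- cs < depth
  if (any(low)) {
    stop("depth ", depth, " exceeds the library size of sample(s): ",
         paste(colnames(x)[low], collapse = ", "), call. = FALSE)
  }
  # rrarefy warns when the smallest nonzero count exceeds 1 (it suspects
  # pre-normalised data); integer counts are already validated above
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(x), sample = depth))))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(x)
  out
}

#' Per-sample relative abundances
#'
#' @param table count table.
#' @return numeric matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(table) {
  x <- as_count_table(table)
  cs <- colSums(x)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ", paste(colnames(x)[cs == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(x, 2, cs, "/")
}

#' Aggregate a count table to a taxonomic rank
#'
#' Sums counts over all taxa sharing the same name at `rank`. Integer
#' arithmetic, so per-sample totals are conserved exactly. Taxa missing a
#' name at the rank are pooled under `unclassified`.
#'
#' @param table count table keyed by taxon id.
#' @param tax taxonomy data frame (see [read_taxonomy()]).
#' @param rank rank column name, e.g. `"phylum"` or `"genus"`.
#' @return count table whose rows are distinct rank names.
#' @export
aggregate_rank <- function(table, tax, rank) {
  x <- as_count_table(table)
  if (!rank %in% names(tax)) {
    stop("unknown rank '", rank, "'; taxonomy has: ",
         paste(setdiff(names(tax), "taxon_id"), collapse = ", "), call. = FALSE)
  }
  idx <- match(rownames(x), tax$taxon_id)
  if (anyNA(idx)) {
    stop("taxa without a lineage entry: ",
         paste(utils::head(rownames(x)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  grp <- as.character(tax[[rank]][idx])
  grp[is.na(grp) | grp == ""] <- "unclassified"
  out <- rowsum(x, group = grp, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Merge low-abundance taxa into an "others" row
#'
#' Taxa whose overall mean relative abundance across all samples falls below
#' `threshold` are pooled into a single `others` row; column sums are
#' preserved. The dataset-wide mean (not a per-sample rule) yields one
#' consistent taxon legend across samples.
#'
#' @param rel relative-abundance matrix (columns sum to 1).
#' @param threshold mean-abundance cutoff, default 0.01 (the "<1%" rule).
#' @param label name of the pooled row.
#' @return relative-abundance matrix, possibly with an `others` row.
#' @export
bin_others <- function(rel, threshold = 0.01, label = "others") {
  rel <- as.matrix(rel)
  if (any(abs(colSums(rel) - 1) > 1e-8)) {
    stop("`rel` columns must sum to 1; call relative_abundance() first", call. = FALSE)
  }
  drop <- rowMeans(rel) < threshold
  if (!any(drop)) return(rel)
  kept <- rel[!drop, , drop = FALSE]
  others <- colSums(rel[drop, , drop = FALSE])
  out <- rbind(kept, matrix(others, nrow = 1, dimnames = list(label, colnames(rel))))
  out
}

#' Distribution of one taxon's reads across habitats
#'
#' Shares of the taxon's total reads contributed by each habitat, as
#' percentages rounded to two decimals (round-half-even).
#'
#' @param table count table.
#' @param info sample metadata.
#' @param taxon taxon id (row name of `table`).
#' @return named numeric vector of percentages over [habitat_levels()]
#'   present in `info`; sums to 100 within rounding.
#' @export
habitat_distribution <- function(table, info, taxon) {
  x <- as_count_table(table)
  info <- validate_sample_info(info, x)
  if (!taxon %in% rownames(x)) stop("taxon '", taxon, "' not in table", call. = FALSE)
  reads <- x[taxon, info$sample_id]
  total <- sum(reads)
  if (total == 0) stop("taxon '", taxon, "' has zero total reads", call. = FALSE)
  habs <- intersect(habitat_levels(), unique(info$habitat))
  by_hab <- vapply(habs, function(h) sum(reads[info$habitat == h]), numeric(1))
  pct(by_hab, total)
}

#' The n most abundant taxa
#'
#' Ranked by total counts over all samples, ties broken lexicographically by
#' taxon id so the ordering is stable across runs.
#'
#' @param table count table.
#' @param n number of taxa to return.
#' @return character vector of taxon ids, most abundant first.
#' @export
top_n_taxa <- function(table, n) {
  x <- as_count_table(table)
  if (n > nrow(x)) stop("n exceeds the number of taxa", call. = FALSE)
  tot <- rowSums(x)
  ord <- order(-tot, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Log10-transformed relative abundances for heatmap export
#'
#' Convenience export: log10 of relative abundance with a pseudocount floor,
#' restricted to the top `n` taxa.
#'
#' @param table count table.
#' @param n number of top taxa to keep.
#' @param floor value replacing zero proportions before the log.
#' @return numeric matrix, `n` taxa x samples.
#' @export
log10_heatmap_matrix <- function(table, n = 40, floor = 1e-6) {
  rel <- relative_abundance(table)
  keep <- top_n_taxa(table, min(n, nrow(rel)))
  log10(pmax(rel[keep, , drop = FALSE], floor))
}
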