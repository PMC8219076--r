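# Count tables are plain integer matrices, taxa in rows and samples in
# columns, in the style of vegan community matrices (transposed). One
# canonical orientation is used in memory and on disk so that write -> read
# round-trips are bit-exact.

#' Validate and canonicalise an OTU/taxon count table
#'
#' A count table is a non-negative integer matrix with unique taxon row names
#' and unique sample column names. Counts arriving as doubles are accepted
#' when integer-valued and stored as integers.
#'
#' @param x matrix (or object coercible to one) of counts, taxa x samples.
#' @return integer matrix with `dimnames`.
#' @export
as_count_table <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table needs taxon row names and sample column names", call. = FALSE)
  }
  dup_t <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_t)) {
    stop("duplicated taxon ids: ", paste(dup_t, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(suppressWarnings(matrix(as.numeric(x), nrow(x)))), arr.ind = TRUE)
    coord <- if (nrow(bad)) {
      sprintf(" (first at taxon '%s', sample '%s')",
              rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]])
    } else ""
    stop("count table contains non-numeric or non-finite cells", coord, call. = FALSE)
  }
  off <- which(x < 0 | abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(off)) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell taxon '%s', sample '%s' (value %s)",
      rownames(x)[off[1, 1]], colnames(x)[off[1, 2]], format(x[off[1, , drop = FALSE]])
    ), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Read a count table from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids (first
#' field is the taxon-id column name) and whose first column holds taxon ids.
#'
#' @param path file path.
#' @return integer count matrix, taxa x samples.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup)) {
    stop("duplicated sample columns in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  taxa <- raw[[1]]
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup)) {
    stop("duplicated taxon ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed numeric cell at taxon '%s', sample '%s' (value '%s')",
                 taxa[bad[1, 1]], samples[bad[1, 2]], vals[bad[1, , drop = FALSE]]),
         call. = FALSE)
  }
  dimnames(num) <- list(taxa, samples)
  as_count_table(num)
}

#' Write a count table to TSV
#'
#' @param table count table (see [as_count_table()]).
#' @param path output file path.
#' @param id_column name of the taxon-id column header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_column = "taxon_id") {
  x <- as_count_table(table)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns `sample_id`, `habitat` (one of water/sediment/intestine), `mode`
#' (MC or RC) and `replicate` are required.
#'
#' @param path file path.
#' @return data frame of sample metadata.
#' @export
read_sample_info <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            stringsAsFactors = FALSE, comment.char = "")
  validate_sample_info(info)
}

#' Validate sample metadata, optionally against a count table
#'
#' @param info data frame with `sample_id`, `habitat`, `mode`, `replicate`.
#' @param table optional count table whose samples must all be described.
#' @return `info`, with `habitat` and `mode` checked against their closed
#'   vocabularies.
#' @export
validate_sample_info <- function(info, table = NULL) {
  need <- c("sample_id", "habitat", "mode", "replicate")
  miss <- setdiff(need, names(info))
  if (length(miss)) stop("sample info lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(info$sample_id)) {
    stop("duplicated sample_id in sample info", call. = FALSE)
  }
  bad <- setdiff(unique(info$habitat), habitat_levels())
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(info$mode), c("MC", "RC"))
  if (length(bad)) stop("unknown mode label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(table)) {
    x <- as_count_table(table)
    miss <- setdiff(colnames(x), info$sample_id)
    if (length(miss)) {
      stop("samples without metadata: ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  info
}

#' Habitat vocabulary in its canonical order
#'
#' The order (water, sediment, intestine) is also the deterministic tie-break
#' order wherever a habitat must be chosen among equals.
#'
#' @return character vector of habitat labels.
#' @export
habitat_levels <- function() c("water", "sediment", "intestine")

#' Write sample metadata to TSV
#' @param info sample metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(info, path) {
  utils::write.table(validate_sample_info(info), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy lineage table from TSV
#'
#' First column `taxon_id`; remaining columns are rank names (at least
#' `phylum` and `genus`). Name strings may carry SILVA-style `norank_` /
#' `unclassified_` prefixes.
#'
#' @param path file path.
#' @return data frame mapping taxon ids to rank names.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tax <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  if (!"taxon_id" %in% names(tax)) stop("taxonomy lacks a taxon_id column", call. = FALSE)
  if (anyDuplicated(tax$taxon_id)) stop("duplicated taxon_id in taxonomy", call. = FALSE)
  tax
}

#' Write a taxonomy table to TSV
#' @param tax taxonomy data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
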