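# Small in-code fixtures shared across test files.

# count table with named dims
ct <- function(values, taxa, samples) {
  m <- matrix(values, nrow = length(taxa), byrow = TRUE,
              dimnames = list(taxa, samples))
  storage.mode(m) <- "integer"
  m
}

# metadata for the standard 18-sample design (ids as emitted by the generator)
design_info <- function() {
  generate_community(synth_config(n_signature = 1, n_shared = 0,
                                  depth_range = c(10, 10), seed = 1))$sample_info
}

# six-group metadata for a hand-built genus table with one sample per group
six_group_info <- function() {
  data.frame(
    sample_id = c("MCw1", "RCw1", "MCs1", "RCs1", "MCc1", "RCc1"),
    habitat = rep(c("water", "sediment", "intestine"), each = 2),
    mode = rep(c("MC", "RC"), 3),
    replicate = 1L,
    stringsAsFactors = FALSE
  )
}

# genus table realising exact environment-presence patterns: `pattern` is a
# named list genus -> character vector of habitats; reads_per_hit reads are
# placed in the first sample of each listed habitat.
presence_table <- function(pattern, info = six_group_info(), reads_per_hit = 5) {
  m <- matrix(0L, length(pattern), nrow(info),
              dimnames = list(names(pattern), info$sample_id))
  for (g in names(pattern)) {
    for (h in pattern[[g]]) {
      s <- info$sample_id[info$habitat == h][1]
      m[g, s] <- as.integer(reads_per_hit)
    }
  }
  m
}

# environment-set patterns with the published cluster counts:
# cluster -> habitats; counts chosen so every printed percentage re-derives.
published_cluster_counts <- function() {
  list(
    `1` = list(envs = "intestine", n = 81),
    `2` = list(envs = c("intestine", "water"), n = 120),
    `3` = list(envs = c("intestine", "water", "sediment"), n = 605),
    `4` = list(envs = c("intestine", "sediment"), n = 75),
    `5` = list(envs = c("water", "sediment"), n = 122),
    `6` = list(envs = "water", n = 102),
    `7` = list(envs = "sediment", n = 102)
  )
}

published_pattern <- function() {
  spec <- published_cluster_counts()
  pattern <- list()
  for (cl in names(spec)) {
    for (i in seq_len(spec[[cl]]$n)) {
      pattern[[sprintf("c%s_g%04d", cl, i)]] <- spec[[cl]]$envs
    }
  }
  pattern
}
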