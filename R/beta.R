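# Bray-Curtis distances, principal coordinates, UPGMA clustering and the
# seeded ANOSIM / PERMANOVA permutation tests.

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on counts, typically after
#' rarefaction. Delegates to [vegan::vegdist()].
#'
#' @param table count table, taxa x samples.
#' @return symmetric numeric matrix with zero diagonal, entries in \[0, 1\],
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  x <- as_count_table(table)
  if (ncol(x) < 2) stop("need at least two samples", call. = FALSE)
  zero <- colSums(x) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(x)[zero], collapse = ", "),
         call. = FALSE)
  }
  as.matrix(vegan::vegdist(t(x), method = "bray"))
}

as_distance_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0)) {
    stop("not a valid distance matrix (square, symmetric, zero diagonal)",
         call. = FALSE)
  }
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("s", seq_len(nrow(m))), paste0("s", seq_len(nrow(m))))
  }
  m
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the double-centred `-D^2/2` matrix (Gower). All
#' eigenvalues are reported (negative ones flag non-Euclidean distances) but
#' only positive-eigenvalue axes carry coordinates, and the proportion of
#' variation explained is taken over the positive eigenvalues only, with no
#' Lingoes/Cailliez correction. Axis signs are fixed by making each axis's
#' largest-magnitude loading positive, so ordinations are reproducible.
#'
#' @param d distance matrix (matrix or `dist`).
#' @return list of class `pcoa_ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (per retained
#'   axis), `trivial` (TRUE when fewer than 3 samples).
#' @export
pcoa <- function(d) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (m^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  eig <- e$values
  tol <- max(abs(eig)) * 1e-9
  keep <- which(eig > tol)
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(eig[keep]), length(keep))
  for (k in seq_len(ncol(coords))) {
    jmax <- which.max(abs(coords[, k]))
    if (coords[jmax, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(m), paste0("Axis", seq_along(keep)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = eig[keep] / sum(eig[keep]),
    trivial = n < 3
  ), class = "pcoa_ordination")
}

#' UPGMA (average-linkage) dendrogram
#'
#' Agglomerates by the unweighted pair-group average; the recorded merge
#' height is HALF the between-cluster average distance, so leaf-to-root path
#' lengths equal half the largest average distance (the ultrametric
#' phylogenetic convention). Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member), making the tree deterministic.
#'
#' @param d distance matrix (matrix or `dist`).
#' @return an `hclust`-compatible object (merge, height, order, labels).
#' @export
upgma <- function(d) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  labels <- rownames(m)
  cl_id <- -(seq_len(n))      # hclust convention: negative = leaf
  cl_size <- rep(1L, n)
  cl_lab <- labels            # lexicographic representative of each cluster
  d_work <- m
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- seq_len(n)

  for (s in seq_len(n - 1L)) {
    k <- length(active)
    dmin <- Inf; best <- NULL
    for (i in seq_len(k - 1L)) {
      for (jj in (i + 1L):k) {
        dij <- d_work[active[i], active[jj]]
        if (is.null(best) || dij < dmin - 1e-12) {
          dmin <- dij; best <- c(i, jj)
        } else if (abs(dij - dmin) <= 1e-12) {
          lab_new <- sort(c(cl_lab[active[i]], cl_lab[active[jj]]))
          lab_old <- sort(c(cl_lab[active[best[1]]], cl_lab[active[best[2]]]))
          if (lab_new[1] < lab_old[1] ||
              (lab_new[1] == lab_old[1] && lab_new[2] < lab_old[2])) {
            best <- c(i, jj)
          }
        }
      }
    }
    a <- active[best[1]]; b <- active[best[2]]
    merge[s, ] <- sort(c(cl_id[a], cl_id[b]))
    height[s] <- d_work[a, b] / 2
    # unweighted average update into slot a
    for (o in setdiff(active, c(a, b))) {
      d_work[a, o] <- d_work[o, a] <-
        (cl_size[a] * d_work[a, o] + cl_size[b] * d_work[b, o]) /
        (cl_size[a] + cl_size[b])
    }
    cl_size[a] <- cl_size[a] + cl_size[b]
    cl_id[a] <- s
    cl_lab[a] <- min(cl_lab[a], cl_lab[b])
    active <- setdiff(active, b)
  }

  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = labels,
                 method = "upgma", dist.method = "user"),
            class = "hclust")
}

#' Export a dendrogram as Newick
#'
#' @param h an `hclust`-style tree, e.g. from [upgma()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

perm_test_result <- function(method, statistic, r_squared, p_value, n_perm,
                             f_model = NA_real_) {
  structure(list(method = method, statistic = statistic, r_squared = r_squared,
                 f_model = f_model, p_value = p_value,
                 n_permutations = n_perm), class = "perm_test_result")
}

check_perm_groups <- function(m, labels) {
  if (length(labels) != nrow(m)) {
    stop("labels must match the number of samples", call. = FALSE)
  }
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2], collapse = ", "),
         call. = FALSE)
  }
  invisible(sizes)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's R on the midranks of the pairwise distances:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`.
#' The p-value is the +1-smoothed permutation estimate
#' `(1 + #{R_perm >= R_obs}) / (n_perm + 1)` (floor 0.001 at 999
#' permutations), or a complete enumeration over all distinct label
#' assignments when `permutations = "exact"`.
#'
#' When the design contains a nuisance factor (e.g. testing breeding mode
#' across samples structured by habitat), `strata` restricts the label
#' permutations to within-stratum shuffles, preserving the observed balance
#' and keeping the test exact under within-stratum exchangeability.
#'
#' @param d distance matrix.
#' @param labels group labels in sample order.
#' @param permutations number of random label permutations, or `"exact"`.
#' @param seed integer seed for the random permutations.
#' @param strata optional vector of stratum labels; permutations shuffle
#'   `labels` only within strata (random permutations only).
#' @return `perm_test_result` with `statistic` = R in \[-1, 1\].
#' @export
anosim_test <- function(d, labels, permutations = 999, seed = NULL,
                        strata = NULL) {
  m <- as_distance_matrix(d)
  labels <- as.character(labels)
  check_perm_groups(m, labels)
  n <- nrow(m)
  pr <- which(upper.tri(m), arr.ind = TRUE)
  ii <- pr[, 1]; jj <- pr[, 2]
  r <- rank(m[upper.tri(m)])
  denom <- n * (n - 1) / 4
  r_stat <- function(lab) {
    w <- lab[ii] == lab[jj]
    (mean(r[!w]) - mean(r[w])) / denom
  }
  obs <- r_stat(labels)
  if (identical(permutations, "exact")) {
    if (!is.null(strata)) {
      stop("exact enumeration is not implemented with strata", call. = FALSE)
    }
    perms <- multiset_permutations(labels)
    stats <- apply(perms, 1, r_stat)
    p <- mean(stats >= obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    shuffle <- permuter(n, strata)
    stats <- with_seed(seed,
      replicate(permutations, r_stat(labels[shuffle()])))
    p <- (1 + sum(stats >= obs - 1e-12)) / (permutations + 1)
    n_perm <- permutations
  }
  perm_test_result("ANOSIM", obs, NA_real_, p, n_perm)
}

# returns a closure drawing one permutation of 1..n, optionally within strata
permuter <- function(n, strata = NULL) {
  if (is.null(strata)) {
    return(function() sample.int(n))
  }
  stopifnot(length(strata) == n)
  idx <- split(seq_len(n), strata)
  function() {
    out <- integer(n)
    for (s in idx) out[s] <- s[sample.int(length(s))]
    out
  }
}

#' One-factor PERMANOVA (Adonis)
#'
#' Partitions the sum of squared distances: `SS_total = sum d_ij^2 / n` over
#' all pairs, `SS_within` summed per group with its own size, pseudo-F
#' `(SS_between/(g-1)) / (SS_within/(n-g))`, `R^2 = SS_between / SS_total`.
#' Permutation p-value as in [anosim_test()]. When `SS_within = 0` the
#' pseudo-F is reported as `Inf`.
#'
#' @inheritParams anosim_test
#' @return `perm_test_result` with `statistic` = pseudo-F and `r_squared`.
#' @export
adonis_test <- function(d, labels, permutations = 999, seed = NULL,
                        strata = NULL) {
  m <- as_distance_matrix(d)
  labels <- as.character(labels)
  check_perm_groups(m, labels)
  n <- nrow(m)
  g <- length(unique(labels))
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(lab) {
    sum(vapply(unique(lab), function(gr) {
      idx <- which(lab == gr)
      sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }, numeric(1)))
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ssb <- ss_total - ssw
    if (ssw <= 1e-300) return(Inf)
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  obs_ssw <- ss_within(labels)
  obs_f <- f_stat(labels)
  r2 <- (ss_total - obs_ssw) / ss_total
  if (identical(permutations, "exact")) {
    if (!is.null(strata)) {
      stop("exact enumeration is not implemented with strata", call. = FALSE)
    }
    perms <- multiset_permutations(labels)
    stats <- apply(perms, 1, f_stat)
    p <- mean(stats >= obs_f - 1e-12)
    n_perm <- nrow(perms)
  } else {
    shuffle <- permuter(n, strata)
    stats <- with_seed(seed,
      replicate(permutations, f_stat(labels[shuffle()])))
    p <- (1 + sum(stats >= obs_f - 1e-12)) / (permutations + 1)
    n_perm <- permutations
  }
  perm_test_result("Adonis", obs_f, r2, p, n_perm, f_model = obs_f)
}

#' Table of ANOSIM/Adonis contrasts in the published layout
#'
#' One row per contrast: the three-habitat comparison plus the within-habitat
#' mode contrasts, each carrying ANOSIM R and p, the permutation count, and
#' Adonis pseudo-F, R-squared and p.
#'
#' @param d distance matrix over all samples.
#' @param info sample metadata.
#' @param permutations permutations per test.
#' @param seed integer master seed; each contrast gets a derived sub-seed.
#' @return data frame with columns `group`, `anosim_R`, `anosim_p`,
#'   `permutations`, `adonis_F`, `adonis_R2`, `adonis_p`.
#' @export
permutation_test_table <- function(d, info, permutations = 999, seed = NULL) {
  m <- as_distance_matrix(d)
  info <- validate_sample_info(info)
  info <- info[match(rownames(m), info$sample_id), ]
  habs <- intersect(habitat_levels(), unique(info$habitat))
  contrasts <- c(list(list(name = paste(habs, collapse = " vs "),
                           samples = seq_len(nrow(m)), labels = info$habitat)),
                 lapply(habs, function(h) {
                   idx <- which(info$habitat == h)
                   list(name = sprintf("MC-%s vs RC-%s", h, h), samples = idx,
                        labels = info$mode[idx])
                 }))
  rows <- lapply(seq_along(contrasts), function(k) {
    ct <- contrasts[[k]]
    sub <- m[ct$samples, ct$samples]
    sk <- if (is.null(seed)) NULL else stage_seed(seed, paste0("permtest", k))
    an <- anosim_test(sub, ct$labels, permutations, seed = sk)
    ad <- adonis_test(sub, ct$labels, permutations, seed = sk)
    data.frame(group = ct$name, anosim_R = an$statistic, anosim_p = an$p_value,
               permutations = an$n_permutations, adonis_F = ad$statistic,
               adonis_R2 = ad$r_squared, adonis_p = ad$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
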