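# Independent brute-force oracles used to validate the implementations.
# Deliberately written from first principles (loops, enumeration, direct
# formula evaluation) rather than reusing any package code path.

bf_coverage <- function(x) {
  f1 <- 0
  for (v in x) if (v == 1) f1 <- f1 + 1
  1 - f1 / sum(x)
}

bf_chao1 <- function(x) {
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

bf_ace <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  abund <- x[x > cutoff]
  if (length(rare) == 0) return(length(abund))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) return(bf_chao1(x))
  acc <- 0
  for (i in 1:cutoff) acc <- acc + i * (i - 1) * sum(rare == i)
  g2 <- (length(rare) / c_ace) * acc / (n_rare * (n_rare - 1)) - 1
  if (g2 < 0) g2 <- 0
  length(abund) + length(rare) / c_ace + (f1 / c_ace) * g2
}

bf_shannon <- function(x) {
  n <- sum(x); h <- 0
  for (v in x) if (v > 0) h <- h - (v / n) * log(v / n)
  h
}

# repeat probability via pair counting (equivalent closed form, different route)
bf_simpson <- function(x) {
  n <- sum(x)
  sum(choose(x, 2)) / choose(n, 2)
}

# random small community profile for estimator checks
random_profile <- function() {
  s <- sample(3:40, 1)
  x <- c(sample(0:3, s, replace = TRUE, prob = c(0.2, 0.4, 0.25, 0.15)),
         sample(4:60, max(1, s %/% 4), replace = TRUE))
  if (sum(x) < 2) x[1] <- 2
  x
}

# ---- graph oracles (adjacency-matrix based, pure R) ----------------------

# distances and shortest-path counts from source s by BFS level expansion
bf_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); sig <- rep(0, n)
  d[s] <- 0; sig[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(A[v, ] > 0)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
        if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sig)
}

bf_graph_metrics <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  # local clustering
  loc <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    loc[i] <- if (k < 2) 0 else sum(A[nb, nb]) / (k * (k - 1))
  }
  # transitivity = 3 triangles / connected triples
  tri3 <- sum(diag(A %*% A %*% A))          # 6 x triangles
  triples <- sum(deg * (deg - 1)) / 2
  trans <- if (triples == 0) 0 else (tri3 / 2) / triples
  # all-pairs BFS
  bfs <- lapply(1:n, bf_bfs, A = A)
  D <- do.call(rbind, lapply(bfs, `[[`, "d"))
  S <- do.call(rbind, lapply(bfs, `[[`, "sigma"))
  # betweenness: pair-dependency sum, endpoints excluded
  bet <- numeric(n)
  for (v in 1:n) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        if (s != v && t != v && is.finite(D[s, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          bet[v] <- bet[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  # giant component: distances within largest reachable set
  comp <- rep(NA_integer_, n); cid <- 0
  for (i in 1:n) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(D[i, ])] <- cid
    }
  }
  giant <- which(comp == which.max(tabulate(comp)))
  dg <- D[giant, giant, drop = FALSE]
  up <- dg[upper.tri(dg)]
  list(degree = deg, clustering = loc, avg_clustering = mean(loc),
       transitivity = trans, betweenness = bet,
       diameter = if (length(up)) max(up) else 0,
       avg_path_length = if (length(up)) mean(up) else 0)
}

expect_graph_metrics_match <- function(g, label) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  oracle <- bf_graph_metrics(A)
  net <- graph_metrics(g)
  expect_equal(unname(net$nodes$degree), unname(oracle$degree), label = label)
  expect_equal(net$nodes$clustering, oracle$clustering, tolerance = 1e-12,
               label = label)
  expect_equal(net$nodes$betweenness, oracle$betweenness, tolerance = 1e-9,
               label = label)
  expect_equal(net$globals$avg_clustering, oracle$avg_clustering,
               tolerance = 1e-12, label = label)
  expect_equal(net$globals$transitivity, oracle$transitivity,
               tolerance = 1e-12, label = label)
  expect_equal(net$globals$diameter, oracle$diameter, label = label)
  expect_equal(net$globals$avg_path_length, oracle$avg_path_length,
               tolerance = 1e-12, label = label)
}

# adjusted Rand index between two labelings, from the contingency table
bf_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- si * sj / np
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny toy distance matrix with labelled samples
toy_dist <- function(coords, ids = NULL) {
  m <- as.matrix(dist(coords))
  ids <- ids %||% paste0("s", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  m
}
`%||%` <- function(x, y) if (is.null(x)) y else x
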