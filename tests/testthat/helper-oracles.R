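# Brute-force oracles, written against the dense adjacency matrix so they
# share no code path with the package implementations.

dense_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

brute_ksum <- function(g) {
  A <- dense_adj(g)
  d <- rowSums(A)
  out <- numeric(nrow(A))
  for (u in seq_len(nrow(A))) {
    for (v in seq_len(ncol(A))) if (A[u, v] > 0) out[u] <- out[u] + d[v]
  }
  stats::setNames(out, rownames(A))
}

brute_k2sum <- function(g) {
  A <- dense_adj(g)
  d <- rowSums(A)
  A2 <- (A %*% A) > 0
  dist2 <- A2 & !(A > 0)
  diag(dist2) <- FALSE
  stats::setNames(as.numeric(dist2 %*% d), rownames(A))
}

# all-pairs shortest directed paths by Floyd-Warshall
brute_distances <- function(g) {
  A <- dense_adj(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  D
}

brute_closeness <- function(g) {
  D <- brute_distances(g)
  n <- nrow(D)
  stats::setNames((n - 1) / rowSums(D), igraph::V(g)$name)
}

brute_eigenvector <- function(g) {
  A <- dense_adj(g)
  ev <- eigen(A)
  i <- which.max(Re(ev$values))
  x <- abs(Re(ev$vectors[, i]))
  stats::setNames(x / sqrt(sum(x^2)), rownames(A))
}

# PageRank by direct linear solve of the stationarity equations
brute_pagerank <- function(g, d = 0.85) {
  A <- dense_adj(g)
  n <- nrow(A)
  rs <- rowSums(A)
  P <- matrix(1 / n, n, n)
  nz <- rs > 0
  P[nz, ] <- A[nz, , drop = FALSE] / rs[nz]
  x <- solve(diag(n) - d * t(P), rep((1 - d) / n, n))
  stats::setNames(x / sum(x), rownames(A))
}

# seeded random directed graph (edges drawn in plain R)
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p, ]
  if (nrow(pairs) == 0) pairs <- data.frame(from = 1L, to = 2L)
  superspreadr:::build_network(as.character(pairs$from), as.character(pairs$to))
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

sort_el <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}
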