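#' Out-degree centrality
#'
#' With edges oriented along the direction of spreading, the degree of
#' interest is the out-degree.
#'
#' @param g A directed `igraph` graph.
#' @return Named integer vector, one entry per node.
#' @export
out_degree <- function(g) {
  igraph::degree(g, mode = "out")
}

#' Neighbourhood centrality (k_sum)
#'
#' Sum of the out-degrees of a node's out-neighbours (nodes at directed
#' distance exactly 1).
#'
#' @param g A directed `igraph` graph.
#' @return Named numeric vector.
#' @export
neighbourhood_sum <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  d <- igraph::degree(g, mode = "out")
  res <- as.numeric(A %*% d)
  names(res) <- igraph::V(g)$name
  res
}

#' Two-hop neighbourhood centrality (k_2sum)
#'
#' Sum of the out-degrees of the nodes at directed distance exactly 2 from
#' each node (distance along out-edges; nodes at distance 0 or 1 excluded).
#'
#' @param g A directed `igraph` graph.
#' @return Named numeric vector.
#' @export
two_hop_neighbourhood_sum <- function(g) {
  d <- igraph::degree(g, mode = "out")
  hop2 <- igraph::ego(g, order = 2, mode = "out", mindist = 2)
  res <- vapply(hop2, function(vs) sum(d[as.integer(vs)]), 0.0)
  names(res) <- igraph::V(g)$name
  res
}

#' Core number (k-shell decomposition)
#'
#' Iterative shell peeling on the total degree (in + out), the common
#' default for directed graphs: a node's core number is the largest k such
#' that it belongs to a maximal subgraph of minimum total degree k.
#'
#' @param g A directed `igraph` graph.
#' @return Named integer vector.
#' @export
core_number <- function(g) {
  igraph::coreness(g, mode = "all")
}

#' Closeness centrality on directed distances
#'
#' For node u, `(N - 1) / sum_v d(u, v)` with d the directed shortest-path
#' length. Requires a strongly connected graph so every distance is finite;
#' run [largest_scc()] first otherwise.
#'
#' @param g A directed, strongly connected `igraph` graph.
#' @param mode `"out"` (default): distances from the node along out-edges,
#'   consistent with spreading reach; `"in"` for the reverse convention.
#' @return Named numeric vector in (0, 1].
#' @export
closeness <- function(g, mode = c("out", "in")) {
  mode <- match.arg(mode)
  if (!igraph::is_connected(g, mode = "strong")) {
    stop("closeness requires a strongly connected graph; run largest_scc() first")
  }
  n <- igraph::vcount(g)
  if (n == 1L) {
    res <- 1.0
    names(res) <- igraph::V(g)$name
    return(res)
  }
  igraph::closeness(g, mode = mode, normalized = TRUE)
}

# Row-normalized out-adjacency as a sparse matrix (dangling rows uniform).
transition_matrix <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  d <- Matrix::rowSums(A)
  n <- nrow(A)
  P <- A
  nz <- d > 0
  P[nz, ] <- A[nz, , drop = FALSE] / d[nz]
  list(P = P, dangling = !nz, n = n)
}

#' PageRank by power iteration
#'
#' Standard PageRank on the directed graph with a damping factor, computed
#' by power iteration to a fixed tolerance. Scores sum to 1. Dangling nodes
#' (no out-edges) redistribute uniformly.
#'
#' @param g A directed `igraph` graph.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1e4).
#' @return Named numeric vector summing to 1.
#' @export
pagerank <- function(g, damping = 0.85, tol = 1e-10, max_iter = 10000L) {
  stopifnot(damping > 0, damping < 1)
  tm <- transition_matrix(g)
  n <- tm$n
  x <- rep(1 / n, n)
  Pt <- Matrix::t(tm$P)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(damping * (Pt %*% x)) +
      damping * sum(x[tm$dangling]) / n + (1 - damping) / n
    resid <- sum(abs(x_new - x))
    x <- x_new
    if (resid < tol) {
      names(x) <- igraph::V(g)$name
      return(x / sum(x))
    }
  }
  stop(sprintf("pagerank did not converge in %d iterations (residual %.3g)",
               max_iter, resid))
}

#' Eigenvector centrality
#'
#' Principal (Perron) eigenvector of the adjacency matrix, nonnegative and
#' of unit Euclidean norm. With the default orientation `"out"` a node
#' scores high if its out-neighbours score high, matching spreading reach
#' (x = A x up to scale). Requires strong connectivity so the Perron vector
#' is unique and strictly positive. Computed with ARPACK (Lanczos/Arnoldi);
#' plain power iteration stalls on near-decoupled community structure,
#' where the two leading eigenvalues almost coincide.
#'
#' @param g A directed, strongly connected `igraph` graph.
#' @param orientation `"out"` (default) or `"in"`.
#' @param tol ARPACK convergence tolerance (default 1e-10).
#' @return Named numeric vector with unit 2-norm.
#' @export
eigenvector <- function(g, orientation = c("out", "in"), tol = 1e-10) {
  orientation <- match.arg(orientation)
  if (!igraph::is_connected(g, mode = "strong")) {
    stop("eigenvector centrality requires a strongly connected graph")
  }
  n <- igraph::vcount(g)
  if (n == 1L) {
    res <- 1.0
    names(res) <- igraph::V(g)$name
    return(res)
  }
  # igraph scores a node by its in-neighbours (x = A'x); flip edges for "out"
  gg <- if (orientation == "out") igraph::reverse_edges(g) else g
  res <- tryCatch(
    igraph::eigen_centrality(gg, directed = TRUE, options = list(tol = tol)),
    error = function(e) stop("eigenvector computation did not converge: ",
                             conditionMessage(e)))
  x <- res$vector
  x <- abs(x) / sqrt(sum(x^2))
  names(x) <- igraph::V(g)$name
  x
}

#' All seven centrality indicators as a table
#'
#' Computes out-degree, neighbourhood sum (k_sum), two-hop neighbourhood sum
#' (k_2sum), core number, closeness, PageRank, and eigenvector centrality
#' for every node. Deterministic given the graph.
#'
#' @param g A directed, strongly connected `igraph` graph.
#' @return A `data.frame` with a `node` column plus the seven indicators.
#' @export
centrality_table <- function(g) {
  data.frame(
    node = igraph::V(g)$name,
    degree = as.numeric(out_degree(g)),
    k_sum = as.numeric(neighbourhood_sum(g)),
    k_2sum = as.numeric(two_hop_neighbourhood_sum(g)),
    core = as.numeric(core_number(g)),
    closeness = as.numeric(closeness(g)),
    pagerank = as.numeric(pagerank(g)),
    eigenvector = as.numeric(eigenvector(g)),
    stringsAsFactors = FALSE
  )
}

#' Names of the seven centrality indicators
#' @return Character vector of indicator column names.
#' @export
centrality_names <- function() {
  c("degree", "k_sum", "k_2sum", "core", "closeness", "pagerank", "eigenvector")
}
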