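#' @useDynLib superspreadr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical node order: numeric if every label parses as a number, else
# C-locale lexicographic. Determinism across runs/platforms is the point.
label_order <- function(labels) {
  suppressWarnings(num <- as.numeric(labels))
  if (!anyNA(num)) order(num, method = "radix") else order(labels, method = "radix")
}

# Rebuild an igraph object with vertices in canonical (sorted-label) order.
canonicalize <- function(g) {
  labs <- igraph::V(g)$name
  ord <- label_order(labs)
  igraph::permute(g, order(ord))
}

#' Read a directed network from a plain-text edge list
#'
#' Parses the whitespace/tab-separated edge-list dialects used by the large
#' public network repositories (KONECT `out.*` files, SNAP `.txt` files):
#' one edge per line, optional comment lines, optional extra columns
#' (timestamps, weights, attributes) which are discarded. The result is a
#' simple directed graph: self-loops are dropped, duplicate edges collapsed,
#' and vertices are stored in a deterministic sorted-label order.
#'
#' @param path Path to the edge-list file.
#' @param comment_chars Character vector of line prefixes to skip
#'   (default `%` for KONECT and `#` for SNAP).
#' @param drop_extra_columns If `TRUE` (default), columns beyond the first
#'   two are ignored; if `FALSE`, lines with more than two tokens are an error.
#' @param undirected If `TRUE`, each input line is expanded into a
#'   bidirectional edge pair (for repositories that store undirected graphs).
#' @return An `igraph` directed graph with character vertex names.
#' @export
read_edge_list <- function(path, comment_chars = c("%", "#"),
                           drop_extra_columns = TRUE, undirected = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  for (cc in comment_chars) {
    keep <- keep & !startsWith(trimws(lines), cc)
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in ", path, ": file is empty or all comments")
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- idx[which(nt < 2L)[1L]]
    stop("malformed edge list line ", bad, " in ", path,
         ": expected at least 2 whitespace-separated tokens")
  }
  if (!drop_extra_columns && any(nt > 2L)) {
    bad <- idx[which(nt > 2L)[1L]]
    stop("line ", bad, " in ", path, " has more than 2 columns")
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  if (undirected) {
    tmp <- from
    from <- c(from, to)
    to <- c(to, tmp)
  }
  build_network(from, to)
}

# Construct a canonical simple directed graph from endpoint label vectors.
build_network <- function(from, to) {
  nodes <- unique(c(from, to))          # before cleaning: a node seen only
                                        # in a self-loop is still a node
  keep <- from != to                    # drop self-loops
  from <- from[keep]; to <- to[keep]
  nodes <- nodes[label_order(nodes)]
  if (length(nodes) == 0L) stop("empty graph: no nodes after cleaning")
  g <- igraph::graph_from_data_frame(
    unique(data.frame(from = from, to = to, stringsAsFactors = FALSE)),
    directed = TRUE, vertices = nodes)
  g
}

#' Extract the largest strongly connected component
#'
#' Returns the induced subgraph on the largest strongly connected component
#' (SCC). Ties in SCC size are broken deterministically by the component
#' containing the smallest node label.
#'
#' @param g A directed `igraph` graph.
#' @return The induced subgraph, vertices in canonical order.
#' @export
largest_scc <- function(g) {
  stopifnot(igraph::vcount(g) > 0)
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest label over the tied components
    labs <- igraph::V(g)$name
    firsts <- vapply(best, function(ci) {
      members <- labs[comp$membership == ci]
      members[label_order(members)][1L]
    }, "")
    best <- best[label_order(firsts)[1L]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  canonicalize(sub)
}

#' Reverse every edge of a directed network
#'
#' Each edge (u, v) becomes (v, u); the node set is unchanged. Applying the
#' operation twice returns the original graph. Used to reorient networks so
#' that edges follow the direction of information flow.
#'
#' @param g A directed `igraph` graph.
#' @return The edge-reversed graph.
#' @export
reverse_edges <- function(g) {
  canonicalize(igraph::reverse_edges(g))
}

#' Write a network as a two-column edge list
#'
#' @param g A directed `igraph` graph.
#' @param path Output file path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Summarise a network
#'
#' @param g A directed `igraph` graph.
#' @return A list with `n_nodes`, `n_edges`, `is_strongly_connected`.
#' @export
graph_summary <- function(g) {
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       is_strongly_connected = igraph::is_connected(g, mode = "strong"))
}
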