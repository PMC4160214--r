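#' Read an undirected simple network from an edge list
#'
#' Parses a plain-text edge list: one edge per line, two whitespace-separated
#' node labels (extra columns are ignored), lines starting with \code{#} and
#' blank lines skipped. The result is always an undirected \emph{simple}
#' graph: link direction is ignored, self-loops are dropped and duplicate
#' (including reversed) edges are collapsed.
#'
#' @param con A file path or connection, or a character vector of lines if
#'   \code{text = TRUE}.
#' @param text If \code{TRUE}, \code{con} is taken to be the lines themselves.
#' @return An undirected simple \code{igraph} graph with character vertex
#'   names. An empty input yields a graph with 0 nodes.
#' @examples
#' g <- read_edge_list(c("# toy", "a b", "b a", "a a", "b c"), text = TRUE)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
read_edge_list <- function(con, text = FALSE) {
  lines <- if (text) as.character(con) else readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- idx[which(nt < 2L)[1L]]
    stop("malformed edge list: line ", bad, " has fewer than 2 fields",
         call. = FALSE)
  }
  el <- cbind(vapply(toks, `[[`, "", 1L), vapply(toks, `[[`, "", 2L))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a plain-text edge list
#'
#' Inverse of [read_edge_list()]: each unordered edge is written exactly once
#' as two whitespace-separated node labels. Reading the output back gives an
#' identical edge set (up to ordering).
#'
#' @param net An undirected \code{igraph} graph.
#' @param con A file path or writable connection.
#' @export
write_edge_list <- function(net, con) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(if (nrow(el)) paste(el[, 1], el[, 2]) else character(0), con)
}

#' Extract the giant component
#'
#' Returns the induced subgraph on the largest connected component. Ties in
#' component size are broken deterministically by the smallest minimal node
#' label within the component.
#'
#' @param net An undirected \code{igraph} graph.
#' @return The giant component as an \code{igraph} graph; an empty graph maps
#'   to itself.
#' @export
giant_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    labs <- node_labels(net)
    minlab <- vapply(best, function(ci) min(labs[comp$membership == ci]), "")
    best <- best[order(minlab)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Common neighbours of a node pair
#'
#' @param net An undirected \code{igraph} graph.
#' @param x,y Node labels (or indices), \code{x != y}.
#' @return Character vector of labels of the nodes adjacent to both.
#' @export
common_neighbors <- function(net, x, y) {
  i <- node_index(net, x)
  j <- node_index(net, y)
  labs <- node_labels(net)
  ni <- as.integer(igraph::neighbors(net, i))
  nj <- as.integer(igraph::neighbors(net, j))
  labs[intersect(ni, nj)]
}

# Vertex labels as character; synthesised from indices when unnamed.
node_labels <- function(net) {
  labs <- igraph::vertex_attr(net, "name")
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(net)))
  as.character(labs)
}

# Resolve a label or index to a 1-based vertex index, with a clear error.
node_index <- function(net, x) {
  if (is.numeric(x)) {
    i <- as.integer(x)
    if (i < 1L || i > igraph::vcount(net)) stop("unknown node: ", x, call. = FALSE)
    return(i)
  }
  i <- match(as.character(x), node_labels(net))
  if (is.na(i)) stop("unknown node: ", x, call. = FALSE)
  i
}

# Integer adjacency list (1-based), one entry per vertex.
adjacency_list <- function(net) {
  lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
}

# All unordered node pairs NOT present as edges of `net`, as a 2-column
# integer matrix. This is the candidate universe U - E of the predictor.
candidate_pairs <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  pairs <- t(utils::combn(n, 2L))
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  linked <- A[pairs] > 0
  pairs[!linked, , drop = FALSE]
}
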