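#' Erdos-Renyi random graph G(n, p)
#'
#' Every unordered node pair is linked independently with probability
#' \code{p}. Nodes are labelled \code{"1"} ... \code{"n"}; isolated nodes are
#' kept. Identical seeds give identical edge sets.
#'
#' @param n Number of nodes (>= 1).
#' @param p Link probability in [0, 1].
#' @param seed Optional integer seed.
#' @return An undirected simple \code{igraph} graph.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  if (n < 1 || p < 0 || p > 1) stop("need n >= 1 and p in [0, 1]", call. = FALSE)
  g <- labelled_empty_graph(n)
  if (n < 2L || p == 0) return(g)
  pairs <- t(utils::combn(n, 2L))
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < p)
  igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Growth starts from a complete seed graph on \code{m + 1} nodes; each new
#' node attaches to \code{m} distinct existing nodes chosen with probability
#' proportional to their current degree (without replacement). The edge
#' count is therefore exactly \eqn{\binom{m+1}{2} + (n - m - 1)m} and the
#' degree distribution is heavy-tailed.
#'
#' @param n Number of nodes.
#' @param m Links added per new node, \code{1 <= m < n}.
#' @param seed Optional integer seed.
#' @return An undirected simple \code{igraph} graph.
#' @export
barabasi_albert <- function(n, m, seed = NULL) {
  if (m < 1 || m >= n) stop("need 1 <= m < n", call. = FALSE)
  deg <- integer(n)
  edges <- utils::combn(m + 1L, 2L)  # seed clique
  deg[seq_len(m + 1L)] <- m
  acc <- list(edges)
  with_seed(seed, {
    for (v in seq.int(m + 2L, length.out = n - m - 1L)) {
      targets <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)])
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
      acc[[length(acc) + 1L]] <- rbind(rep(v, m), targets)
    }
  })
  igraph::add_edges(labelled_empty_graph(n), do.call(cbind, acc))
}

#' Watts-Strogatz small-world graph
#'
#' A ring lattice on \code{n} nodes, each linked to its \code{k/2} nearest
#' neighbours on either side, with every edge's far endpoint rewired with
#' probability \code{beta} to a uniformly random node, avoiding self-loops
#' and duplicate edges (an edge with no admissible target is kept). The edge
#' count is always exactly \eqn{nk/2}.
#'
#' @param n Number of nodes.
#' @param k Even lattice degree, \code{k < n}.
#' @param beta Rewiring probability in [0, 1].
#' @param seed Optional integer seed.
#' @return An undirected simple \code{igraph} graph.
#' @export
watts_strogatz <- function(n, k, beta, seed = NULL) {
  if (k %% 2 != 0 || k >= n || k < 2) stop("need even k with 2 <= k < n", call. = FALSE)
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]", call. = FALSE)
  adj <- vector("list", n)
  for (v in seq_len(n)) {
    adj[[v]] <- sort(unique((v - 1L + c(seq_len(k / 2), n - seq_len(k / 2))) %% n + 1L))
  }
  rewire_one <- function(u, v) {
    cand <- setdiff(seq_len(n), c(u, adj[[u]]))
    if (length(cand) == 0L) return(v)
    cand[sample.int(length(cand), 1L)]
  }
  with_seed(seed, {
    for (u in seq_len(n)) {
      for (v in adj[[u]]) {
        if (v <= u) next  # visit each undirected edge once
        if (beta > 0 && stats::runif(1) < beta) {
          w <- rewire_one(u, v)
          if (w != v) {
            adj[[u]] <- c(setdiff(adj[[u]], v), w)
            adj[[v]] <- setdiff(adj[[v]], u)
            adj[[w]] <- c(adj[[w]], u)
          }
        }
      }
    }
  })
  edges <- do.call(cbind, lapply(seq_len(n), function(u) {
    vs <- adj[[u]][adj[[u]] > u]
    if (length(vs)) rbind(u, vs) else NULL
  }))
  g <- labelled_empty_graph(n)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Small named fixture graphs
#'
#' Deterministic hand-specified graphs used throughout the documentation and
#' tests: \code{"triangle"}; \code{"path3"} (a-b-c) and \code{"path4"};
#' \code{"star4"} (centre \code{z} with leaves \code{u,v,w});
#' \code{"cycle4"}; and \code{"k4_minus_edge"}, the complete graph on nodes
#' 1-4 with the edge (3,4) removed — its sole candidate pair (3,4) is the
#' standard worked example for the mutual-information score.
#'
#' @param name Fixture name.
#' @return An undirected simple \code{igraph} graph.
#' @export
fixture_graph <- function(name) {
  specs <- list(
    triangle = c("a", "b", "b", "c", "c", "a"),
    path3 = c("a", "b", "b", "c"),
    path4 = c("a", "b", "b", "c", "c", "d"),
    star4 = c("z", "u", "z", "v", "z", "w"),
    cycle4 = c("a", "b", "b", "c", "c", "d", "d", "a"),
    k4_minus_edge = c("1", "2", "1", "3", "1", "4", "2", "3", "2", "4")
  )
  if (!name %in% names(specs)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  }
  igraph::graph_from_edgelist(matrix(specs[[name]], ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

# Empty undirected graph with vertices named "1".."n".
labelled_empty_graph <- function(n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
}
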