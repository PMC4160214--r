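#' Structural summary statistics of a connected network
#'
#' Computes the standard one-row structural profile of a (giant component of
#' a) network: size \eqn{N}, link count \eqn{M}, network efficiency
#' \eqn{e} (mean of \eqn{1/d_{ij}} over ordered pairs), average local
#' clustering coefficient \eqn{C} (nodes of degree < 2 contribute 0),
#' degree-assortativity coefficient \eqn{r} (Pearson correlation of excess
#' degrees across edge ends), degree heterogeneity
#' \eqn{H = \langle k^2 \rangle / \langle k \rangle^2}, average degree and
#' average shortest distance (mean over unordered pairs).
#'
#' @param net A \emph{connected} undirected simple \code{igraph} graph; run
#'   [giant_component()] first if needed. Disconnected input is an error
#'   (distances would be undefined).
#' @return A one-row \code{data.frame} with columns \code{n}, \code{m},
#'   \code{efficiency}, \code{clustering}, \code{assortativity} (\code{NA}
#'   for regular graphs, where it is 0/0), \code{heterogeneity},
#'   \code{avg_degree}, \code{avg_distance}.
#' @export
summary_stats <- function(net) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  if (n < 2L || !igraph::is_connected(net)) {
    stop("summary_stats needs a connected graph with >= 2 nodes; ",
         "extract the giant component first", call. = FALSE)
  }
  d <- igraph::distances(net)  # BFS, unweighted
  off <- d[upper.tri(d)]
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  q <- excess_degree_distribution(net)
  r <- if (q$sd == 0) NA_real_ else {
    ends <- igraph::as_edgelist(net, names = FALSE)
    j1 <- deg[ends[, 1L]] - 1
    j2 <- deg[ends[, 2L]] - 1
    # both orientations of every edge; identical to the q-moment form
    (mean(j1 * j2) - q$mean^2) / q$sd^2
  }
  data.frame(n = n, m = igraph::ecount(net),
             efficiency = mean(1 / off),
             clustering = mean(cc),
             assortativity = r,
             heterogeneity = mean(deg^2) / mean(deg)^2,
             avg_degree = mean(deg),
             avg_distance = mean(off))
}

#' Excess-degree distribution at a random edge end
#'
#' The excess degree of a node is its degree minus one. Sampling a uniformly
#' random end of a uniformly random edge, the probability of excess degree
#' \eqn{j} is proportional to the number of edge ends at degree-\eqn{(j+1)}
#' nodes. This distribution underlies degree assortativity.
#'
#' @param net An undirected \code{igraph} graph with at least one edge.
#' @return A list with the support \code{j}, probabilities \code{q}
#'   (summing to 1), and the distribution's \code{mean} and \code{sd}.
#' @export
excess_degree_distribution <- function(net) {
  deg <- igraph::degree(net)
  if (igraph::ecount(net) < 1L) stop("graph has no edges", call. = FALSE)
  deg <- deg[deg > 0]
  ends <- rep(deg - 1, deg)  # each node contributes `degree` edge ends
  tab <- table(ends)
  j <- as.integer(names(tab))
  q <- as.numeric(tab) / length(ends)
  mu <- sum(j * q)
  list(j = j, q = q, mean = mu, sd = sqrt(sum(j^2 * q) - mu^2))
}

#' Local assortativity of nodes
#'
#' A per-node decomposition of the assortativity coefficient:
#' \deqn{\rho_v = \frac{(j_v + 1)(j_v \bar{k}_v - \mu_q^2)}{2 M \sigma_q^2},}
#' where \eqn{j_v} is the excess degree of \eqn{v}, \eqn{\bar{k}_v} the mean
#' excess degree of its neighbours, and \eqn{\mu_q, \sigma_q} the moments of
#' the excess-degree distribution. The node values sum exactly to the global
#' assortativity coefficient \eqn{r}, separating locally assortative from
#' locally disassortative nodes even when the global \eqn{r} is near zero.
#'
#' @param net An undirected \code{igraph} graph.
#' @param v Optional node label(s) or index(es); by default all nodes.
#' @return Numeric vector of \eqn{\rho_v}, named by node label. On a regular
#'   graph (\eqn{\sigma_q = 0}) the quantity is the same 0/0 degeneracy as
#'   \eqn{r}, and \code{NA} is returned for every node.
#' @export
local_assortativity <- function(net, v = NULL) {
  deg <- igraph::degree(net)
  M <- igraph::ecount(net)
  q <- excess_degree_distribution(net)
  labs <- node_labels(net)
  if (q$sd == 0) {
    rho <- rep(NA_real_, igraph::vcount(net))
  } else {
    adj <- adjacency_list(net)
    j <- deg - 1
    kbar <- vapply(adj, function(nb) {
      if (length(nb) == 0L) 0 else mean(j[nb])
    }, 0)
    rho <- (j + 1) * (j * kbar - q$mean^2) / (2 * M * q$sd^2)
    rho[deg == 0] <- 0  # isolated nodes sit at no edge end
  }
  names(rho) <- labs
  if (is.null(v)) return(rho)
  rho[vapply(v, node_index, 0L, net = net)]
}

#' Cumulative distribution of local assortativity
#'
#' The fraction of nodes whose local assortativity is at most \eqn{x},
#' evaluated on a grid (by default the sorted node values themselves): a
#' non-decreasing step function from 0 to 1 used to profile how assortative
#' mixing is spread across a network.
#'
#' @inheritParams local_assortativity
#' @param grid Optional numeric vector of evaluation points.
#' @return A \code{data.frame} with columns \code{x} and \code{cdf}.
#' @export
local_assortativity_cdf <- function(net, grid = NULL) {
  rho <- local_assortativity(net)
  if (anyNA(rho)) stop("local assortativity undefined (regular graph)", call. = FALSE)
  if (is.null(grid)) grid <- sort(unique(rho))
  data.frame(x = grid,
             cdf = vapply(grid, function(x) mean(rho <= x), 0))
}
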