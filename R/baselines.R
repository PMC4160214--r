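#' Common Neighbours score
#'
#' \eqn{s_{xy} = |O_{xy}|}: the number of shared neighbours.
#'
#' @param net An undirected \code{igraph} graph.
#' @param x,y Distinct node labels or indices.
#' @export
cn_score <- function(net, x, y) {
  length(common_neighbors(net, x, y))
}

#' Resource Allocation score
#'
#' \eqn{s_{xy} = \sum_{z \in O_{xy}} 1/k_z}: each common neighbour passes on
#' a unit of resource split equally among its neighbours, so low-degree
#' common neighbours weigh more.
#'
#' @inheritParams cn_score
#' @export
ra_score <- function(net, x, y) {
  cn <- common_neighbors(net, x, y)
  if (length(cn) == 0L) return(0)
  sum(1 / igraph::degree(net, cn))
}

#' Network-wide constant of the local naive Bayes model
#'
#' The prior odds that a uniformly chosen node pair is disconnected:
#' \eqn{s = (N(N-1)/2 - M) / M}. It depends only on the size and link count
#' of the (training) graph and decreases as the graph gets denser.
#'
#' @param net An undirected \code{igraph} graph with at least one edge.
#' @export
lnb_constant <- function(net) {
  n <- igraph::vcount(net)
  M <- igraph::ecount(net)
  if (M < 1) stop("lnb_constant needs a graph with at least one edge", call. = FALSE)
  (n * (n - 1) / 2 - M) / M
}

#' Per-node role factor of the local naive Bayes model
#'
#' \eqn{R_z = (N_{\Delta z} + 1) / (N_{\Lambda z} + 1)}, the add-one-smoothed
#' odds that a pair of \eqn{z}'s neighbours is connected; the counts are the
#' same triad counts used by the clustering conditional.
#'
#' @inheritParams cn_score
#' @param z A node label or index.
#' @export
lnb_role_factor <- function(net, z) {
  cnt <- neighbor_pair_counts(net, z)
  (cnt[["triad"]] + 1) / (cnt[["open"]] + 1)
}

#' Local naive Bayes Common Neighbours score
#'
#' \eqn{s_{xy} = \sum_{z \in O_{xy}} \log_2(s \cdot R_z)}: common neighbours
#' are weighted by the (log) posterior odds that they witness a true link,
#' combining the global sparsity constant \eqn{s} with each node's role
#' factor. Zero for pairs with no common neighbours.
#'
#' @inheritParams cn_score
#' @export
lnb_cn_score <- function(net, x, y) {
  cn <- common_neighbors(net, x, y)
  if (length(cn) == 0L) return(0)
  s <- lnb_constant(net)
  sum(vapply(cn, function(z) log2(s * lnb_role_factor(net, z)), 0))
}

#' Local naive Bayes Resource Allocation score
#'
#' As [lnb_cn_score()] with each common neighbour's log-odds term weighted by
#' \eqn{1/k_z}.
#'
#' @inheritParams cn_score
#' @export
lnb_ra_score <- function(net, x, y) {
  cn <- common_neighbors(net, x, y)
  if (length(cn) == 0L) return(0)
  s <- lnb_constant(net)
  k <- igraph::degree(net, cn)
  sum(vapply(cn, function(z) log2(s * lnb_role_factor(net, z)), 0) / k)
}

#' CAR score (common neighbours times links among them)
#'
#' \eqn{s_{xy} = |O_{xy}| \cdot \sum_{z \in O_{xy}} |\gamma(z)| / 2} where
#' \eqn{\gamma(z) = \Gamma(z) \cap O_{xy}} is the part of \eqn{z}'s
#' neighbourhood inside the pair's common-neighbour set. The sum counts the
#' links among the common neighbours, so any pair whose common neighbours
#' form no links — in particular any pair with fewer than two common
#' neighbours — scores 0.
#'
#' @inheritParams cn_score
#' @export
car_score <- function(net, x, y) {
  i <- node_index(net, x); j <- node_index(net, y)
  adj <- adjacency_list(net)
  cn <- intersect(adj[[i]], adj[[j]])
  if (length(cn) < 2L) return(0)
  gamma <- vapply(cn, function(z) length(intersect(adj[[z]], cn)), 0L)
  length(cn) * sum(gamma) / 2
}

#' CRA score (resource-allocation variant of CAR)
#'
#' \eqn{s_{xy} = \sum_{z \in O_{xy}} |\gamma(z)| / k_z}, with
#' \eqn{\gamma(z)} as in [car_score()].
#'
#' @inheritParams cn_score
#' @export
cra_score <- function(net, x, y) {
  i <- node_index(net, x); j <- node_index(net, y)
  adj <- adjacency_list(net)
  cn <- intersect(adj[[i]], adj[[j]])
  if (length(cn) < 2L) return(0)
  gamma <- vapply(cn, function(z) length(intersect(adj[[z]], cn)), 0L)
  sum(gamma / lengths(adj)[cn])
}
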