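#' Degree-based prior probability that a node pair is disconnected
#'
#' Under the assumption of no degree-degree correlation, the probability that
#' a pair with training degrees \eqn{k_x, k_y} in a graph of \eqn{M} training
#' links is \emph{not} connected is
#' \deqn{p(L^0_{xy}) = \binom{M-k_x}{k_y} / \binom{M}{k_y},}
#' which is symmetric in \eqn{(k_x, k_y)} and non-increasing in each degree.
#' Binomial coefficients are evaluated in log-space so large \eqn{M} cannot
#' overflow.
#'
#' @param kx,ky Non-negative node degrees (vectorised).
#' @param M Number of links in the training graph (\eqn{M \ge 1}).
#' @return Probabilities in \eqn{[0, 1]}.
#' @examples
#' disconnection_prior(3, 2, 10)  # 7/15
#' @export
disconnection_prior <- function(kx, ky, M) {
  if (any(kx < 0) || any(ky < 0) || any(M < 1)) {
    stop("degrees must be >= 0 and M >= 1", call. = FALSE)
  }
  exp(lchoose(M - kx, ky) - lchoose(M, ky))
}

#' Self-information of a link, in bits
#'
#' \eqn{I(L^1_{xy}) = -\log_2(1 - p(L^0_{xy}))}: the information content of
#' observing a link between nodes of the given degrees. When the prior leaves
#' no probability for the link (e.g. a degree-0 endpoint) the result is
#' \code{Inf}, an ordered sentinel that ranks such pairs below all others.
#'
#' @inheritParams disconnection_prior
#' @return Self-information in bits, \eqn{\ge 0} (possibly \code{Inf}).
#' @export
link_self_information <- function(kx, ky, M) {
  -log2(1 - disconnection_prior(kx, ky, M))
}

#' Connected and disconnected neighbour-pair counts of a node
#'
#' For node \eqn{z}, counts the unordered pairs of its neighbours that are
#' themselves linked (\eqn{N_{\Delta z}}, closed triads through \eqn{z}) and
#' unlinked (\eqn{N_{\Lambda z}}). Their sum is \eqn{\binom{k_z}{2}}.
#'
#' @param net An undirected \code{igraph} graph.
#' @param z A node label or index.
#' @return Named numeric vector \code{c(triad =, open =)}.
#' @export
neighbor_pair_counts <- function(net, z) {
  i <- node_index(net, z)
  nb <- as.integer(igraph::neighbors(net, i))
  k <- length(nb)
  if (k < 2L) return(c(triad = 0, open = 0))
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  tri <- sum(A[nb, nb]) / 2
  c(triad = tri, open = k * (k - 1) / 2 - tri)
}

#' Clustering-based conditional link probability at a common neighbour
#'
#' The probability that two neighbours of \eqn{z} are linked, given \eqn{z}
#' is their common neighbour, estimated by \eqn{z}'s local clustering
#' coefficient \eqn{C_z = N_{\Delta z} / (N_{\Delta z} + N_{\Lambda z})}.
#' Undefined for degree < 2; returns \code{NA} there.
#'
#' @inheritParams neighbor_pair_counts
#' @return A probability in \eqn{[0, 1]}, or \code{NA} when \eqn{k_z < 2}.
#' @export
clustering_conditional <- function(net, z) {
  cnt <- neighbor_pair_counts(net, z)
  tot <- cnt[["triad"]] + cnt[["open"]]
  if (tot == 0) return(NA_real_)
  cnt[["triad"]] / tot
}

#' Average mutual information carried by a node as a common neighbour
#'
#' For node \eqn{z}, the mean over all unordered neighbour pairs
#' \eqn{\{m, n\} \subseteq \Gamma(z)} of
#' \eqn{I(L^1_{mn}) - I(L^1_{mn} \mid z)}, where the conditional
#' self-information is \eqn{-\log_2 C_z}. This measures how much knowing that
#' \eqn{z} is a common neighbour reduces the uncertainty of a link, and may
#' be negative for weakly clustered nodes. By stipulation the contribution is
#' 0 when \eqn{C_z = 0} (no closed triads, so the conditional term would be
#' infinite) and \eqn{I(z) = 0} when \eqn{k_z < 2}.
#'
#' @inheritParams neighbor_pair_counts
#' @return Mutual information in bits (may be negative).
#' @export
node_mutual_information <- function(net, z) {
  i <- node_index(net, z)
  mi_node_information(net)[i]
}

# I(z) for every node at once. Degrees and M are those of `net`, which in
# evaluation is always the training graph: probe links never leak in.
mi_node_information <- function(net) {
  deg <- igraph::degree(net)
  M <- igraph::ecount(net)
  n <- igraph::vcount(net)
  adj <- adjacency_list(net)
  # local clustering = C_z; isolated / degree-1 nodes get NaN from igraph
  cz <- igraph::transitivity(net, type = "localundirected", isolates = "NaN")
  iz <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L || is.nan(cz[v]) || cz[v] == 0) next  # stipulation: I(z) = 0
    pr <- utils::combn(nb, 2L)
    prior_bits <- link_self_information(deg[pr[1L, ]], deg[pr[2L, ]], M)
    iz[v] <- mean(prior_bits - (-log2(cz[v])))
  }
  iz
}

#' Mutual-information link score of a node pair
#'
#' The likelihood score
#' \deqn{s_{xy} = \sum_{z \in O_{xy}} I(z) - I(L^1_{xy}),}
#' combining the degree-prior self-information of the link with the mutual
#' information contributed by each common neighbour (assumed independent).
#' With no common neighbours the score reduces to \eqn{-I(L^1_{xy})}, so
#' unlike common-neighbour counts the index still discriminates such pairs by
#' their degrees. Scores are in bits, may be negative, and only their
#' relative order matters; a pair with a degree-0 endpoint scores \code{-Inf}.
#'
#' @param net An undirected \code{igraph} graph (the training graph).
#' @param x,y Distinct node labels or indices.
#' @return The score in bits.
#' @examples
#' g <- fixture_graph("k4_minus_edge")
#' mi_score(g, "3", "4")  # about -1.1388
#' @export
mi_score <- function(net, x, y) {
  i <- node_index(net, x)
  j <- node_index(net, y)
  if (i == j) stop("x and y must be distinct nodes", call. = FALSE)
  iz <- mi_node_information(net)
  deg <- igraph::degree(net)
  M <- igraph::ecount(net)
  cn <- intersect(as.integer(igraph::neighbors(net, i)),
                  as.integer(igraph::neighbors(net, j)))
  unname(sum(iz[cn]) - link_self_information(deg[[i]], deg[[j]], M))
}

#' Per-node information table for a training graph
#'
#' Precomputes, for every node, the quantities the mutual-information index
#' needs: degree, connected/disconnected neighbour-pair counts, the
#' clustering conditional \eqn{C_z} and the average mutual information
#' \eqn{I(z)}. Computing scores from this table is exactly equivalent to the
#' direct per-pair computation.
#'
#' @param net An undirected \code{igraph} graph.
#' @return A \code{data.frame} with columns \code{node}, \code{degree},
#'   \code{n_triad}, \code{n_open}, \code{c_z} (\code{NA} when degree < 2)
#'   and \code{i_z} (bits).
#' @export
mi_score_table <- function(net) {
  deg <- igraph::degree(net)
  cz <- igraph::transitivity(net, type = "localundirected", isolates = "NaN")
  cz[is.nan(cz)] <- NA_real_
  tri <- vapply(seq_len(igraph::vcount(net)),
                function(v) neighbor_pair_counts(net, v)[["triad"]], 0)
  data.frame(node = node_labels(net),
             degree = as.numeric(deg),
             n_triad = tri,
             n_open = deg * (deg - 1) / 2 - tri,
             c_z = cz,
             i_z = mi_node_information(net),
             stringsAsFactors = FALSE)
}
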