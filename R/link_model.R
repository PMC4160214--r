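#' Fit a link-prediction index to a training graph
#'
#' Builds a scorer for candidate (non-linked) node pairs from the topology of
#' a training graph. The fitted object caches everything the chosen index
#' needs — degrees, the link count \eqn{M}, and per-node quantities such as
#' the average mutual information \eqn{I(z)} or the naive-Bayes role factors
#' — so that [predict.link_model()] can rank many pairs cheaply. All
#' quantities come from the training graph alone; links held out for
#' evaluation never leak into the scores.
#'
#' Available indices: \code{"MI"} (mutual information, the package's core),
#' \code{"CN"}, \code{"RA"}, \code{"LNB-CN"}, \code{"LNB-RA"}, \code{"CAR"},
#' \code{"CRA"}, plus \code{"random"}, a chance baseline of i.i.d. uniform
#' scores used to calibrate evaluation at AUC 0.5.
#'
#' @param net An undirected simple \code{igraph} graph (the training graph).
#' @param index Index name (case-insensitive), see Details.
#' @return An object of class \code{"link_model"} with \code{print},
#'   \code{summary}, \code{predict} and \code{plot} methods.
#' @examples
#' g <- fixture_graph("k4_minus_edge")
#' fit <- link_model(g, "MI")
#' predict(fit)  # the single candidate pair (3,4) and its score in bits
#' @seealso [rank_candidates()], [run_experiment()]
#' @export
link_model <- function(net, index = "MI") {
  stopifnot(igraph::is_igraph(net), !igraph::is_directed(net))
  idx <- match_index(index)
  deg <- as.numeric(igraph::degree(net))
  M <- igraph::ecount(net)
  obj <- list(graph = net, index = idx, index_label = toupper(index),
              n = igraph::vcount(net), M = M,
              degrees = deg, labels = node_labels(net))
  # per-common-neighbour additive weight w_z, where the index admits one
  obj$weights <- switch(idx,
    mi = mi_node_information(net),
    cn = rep(1, obj$n),
    ra = ifelse(deg > 0, 1 / deg, 0),
    lnb_cn = ,
    lnb_ra = {
      s <- lnb_constant(net)
      w <- vapply(seq_len(obj$n),
                  function(z) log2(s * lnb_role_factor(net, z)), 0)
      if (idx == "lnb_ra") w <- ifelse(deg > 0, w / deg, 0)
      w
    },
    NULL)
  if (idx == "mi") obj$node_info <- mi_score_table(net)
  class(obj) <- "link_model"
  obj
}

# Score a 2-column integer matrix of node-index pairs under a fitted model.
# Weight-sum indices use one sparse matrix product; CAR/CRA enumerate each
# pair's common-neighbour set directly.
score_pairs <- function(object, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  idx <- object$index
  if (idx == "random") return(stats::runif(nrow(pairs)))
  if (idx %in% c("car", "cra")) {
    adj <- adjacency_list(object$graph)
    deg <- object$degrees
    return(vapply(seq_len(nrow(pairs)), function(r) {
      cn <- intersect(adj[[pairs[r, 1L]]], adj[[pairs[r, 2L]]])
      if (length(cn) < 2L) return(0)
      gam <- vapply(cn, function(z) length(intersect(adj[[z]], cn)), 0L)
      if (idx == "car") length(cn) * sum(gam) / 2 else sum(gam / deg[cn])
    }, 0))
  }
  A <- igraph::as_adjacency_matrix(object$graph, sparse = TRUE)
  S <- Matrix::crossprod(A, A * object$weights)  # S_ij = sum_{z in O_ij} w_z
  sc <- S[pairs]
  if (idx == "mi") {
    sc <- sc - link_self_information(object$degrees[pairs[, 1L]],
                                     object$degrees[pairs[, 2L]], object$M)
  }
  as.numeric(sc)
}

#' Score and rank candidate node pairs
#'
#' @param object A fitted \code{"link_model"}.
#' @param pairs Optional two-column matrix or data frame of node labels to
#'   score. By default every non-linked pair of the training graph (the
#'   candidate universe) is scored.
#' @param top Optionally keep only the \code{top} highest-scoring pairs.
#' @param ... Unused.
#' @return A \code{data.frame} with columns \code{node1}, \code{node2} and
#'   \code{score}, sorted by decreasing score; ties are broken by the
#'   lexicographic order of the pair labels, so rankings are deterministic.
#' @export
predict.link_model <- function(object, pairs = NULL, top = NULL, ...) {
  labs <- object$labels
  if (is.null(pairs)) {
    ip <- candidate_pairs(object$graph)
  } else {
    pairs <- as.matrix(pairs)
    ip <- cbind(vapply(pairs[, 1L], node_index, 0L, net = object$graph),
                vapply(pairs[, 2L], node_index, 0L, net = object$graph))
  }
  sc <- score_pairs(object, ip)
  l1 <- pmin(labs[ip[, 1L]], labs[ip[, 2L]])
  l2 <- pmax(labs[ip[, 1L]], labs[ip[, 2L]])
  out <- data.frame(node1 = l1, node2 = l2, score = sc,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Rank all candidate links of a training graph under a named index
#'
#' Convenience wrapper: fits [link_model()] and ranks every non-linked node
#' pair in descending score order (deterministic tie-break by pair label).
#'
#' @param train_net The training graph.
#' @param index Index name, see [link_model()].
#' @return A ranked \code{data.frame} as from [predict.link_model()].
#' @export
rank_candidates <- function(train_net, index = "MI") {
  predict(link_model(train_net, index))
}

#' @export
print.link_model <- function(x, ...) {
  cat("Link-prediction model\n")
  cat("  index:", x$index_label, "\n")
  cat("  training graph: N =", x$n, "nodes, M =", x$M, "links\n")
  invisible(x)
}

#' @export
summary.link_model <- function(object, top = 5L, ...) {
  ranked <- predict(object, top = top)
  out <- list(model = object, top = ranked)
  class(out) <- "summary.link_model"
  out
}

#' @export
print.summary.link_model <- function(x, ...) {
  print(x$model)
  cat("  top candidate links:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Histogram of candidate-link scores
#'
#' Plots the distribution of scores over all candidate pairs; infinite
#' sentinel scores (pairs with a degree-0 endpoint under MI) are dropped
#' with a message.
#'
#' @param x A fitted \code{"link_model"}.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.link_model <- function(x, ...) {
  sc <- predict(x)$score
  if (any(!is.finite(sc))) {
    message(sum(!is.finite(sc)), " pairs with infinite score omitted")
    sc <- sc[is.finite(sc)]
  }
  graphics::hist(sc, main = paste(x$index_label, "candidate scores"),
                 xlab = "score", ...)
  invisible(x)
}
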