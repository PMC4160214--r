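#' Split a network's links into training and probe sets
#'
#' Removes a random fraction of the observed links to serve as the probe set
#' (the "missing links" ground truth); the remainder is the training graph.
#' All nodes are kept in the training graph, so nodes can end up with degree
#' 0 there — the MI index then assigns their pairs the \code{-Inf} sentinel.
#' Training connectivity is deliberately not enforced: the split is a plain
#' uniform random division.
#'
#' @param net An undirected simple \code{igraph} graph with at least 2 edges.
#' @param probe_fraction Fraction of links to hide, in (0, 1); default 0.1
#'   (a 90/10 division).
#' @param seed Optional integer seed; equal seeds give identical splits.
#' @return An object of class \code{"train_probe_split"}: a list with the
#'   training graph \code{train}, the probe edges \code{probe} (two-column
#'   character matrix), and the call parameters.
#' @export
split_train_probe <- function(net, probe_fraction = 0.1, seed = NULL) {
  stopifnot(igraph::is_igraph(net))
  if (probe_fraction <= 0 || probe_fraction >= 1) {
    stop("probe_fraction must be in (0, 1)", call. = FALSE)
  }
  M <- igraph::ecount(net)
  if (M < 2) stop("need at least 2 edges to split", call. = FALSE)
  n_probe <- round(probe_fraction * M)
  probe_ids <- with_seed(seed, sample.int(M, n_probe))
  el <- igraph::as_edgelist(net, names = TRUE)
  train <- igraph::delete_edges(net, probe_ids)
  out <- list(train = train,
              probe = el[probe_ids, , drop = FALSE],
              probe_fraction = probe_fraction, seed = seed,
              M = M, n_probe = n_probe)
  class(out) <- "train_probe_split"
  out
}

#' @export
print.train_probe_split <- function(x, ...) {
  cat("Train/probe split:", x$M - x$n_probe, "training links,",
      x$n_probe, "probe links (fraction", x$probe_fraction, ")\n")
  invisible(x)
}

# Locate the probe rows inside a ranked candidate table.
probe_positions <- function(split, scored) {
  keys <- pair_key(scored$node1, scored$node2)
  pk <- pair_key(split$probe[, 1L], split$probe[, 2L])
  m <- match(pk, keys)
  if (anyNA(m)) stop("scored table does not cover all probe pairs", call. = FALSE)
  m
}

#' AUC of a ranking against a probe set
#'
#' The probability that a randomly chosen probe (missing) link scores higher
#' than a randomly chosen non-existent link, with ties credited 1/2:
#' \eqn{(n' + 0.5\,n'') / n}. \code{mode = "exact"} evaluates every
#' probe-by-non-existent comparison through a rank-sum formulation;
#' \code{mode = "sampled"} draws \code{n} independent comparison pairs and is
#' the stochastic estimator that converges to the exact value.
#'
#' @param split A [split_train_probe()] result.
#' @param scored A ranked candidate table from [rank_candidates()] covering
#'   every non-training pair.
#' @param mode \code{"exact"} (default) or \code{"sampled"}.
#' @param n Number of sampled comparisons (required for sampled mode).
#' @param seed Optional seed for sampled mode.
#' @return The AUC in [0, 1].
#' @export
auc_score <- function(split, scored, mode = c("exact", "sampled"),
                      n = NULL, seed = NULL) {
  mode <- match.arg(mode)
  pos <- probe_positions(split, scored)
  s_probe <- scored$score[pos]
  s_none <- scored$score[-pos]
  if (length(s_probe) == 0L || length(s_none) == 0L) {
    stop("both probe and non-existent sets must be non-empty", call. = FALSE)
  }
  if (mode == "exact") {
    r <- rank(c(s_probe, s_none))  # average ranks credit ties 0.5
    np <- length(s_probe)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(s_none))
  } else {
    if (is.null(n)) stop("sampled mode requires n", call. = FALSE)
    with_seed(seed, {
      a <- sample(s_probe, n, replace = TRUE)
      b <- sample(s_none, n, replace = TRUE)
      mean((a > b) + 0.5 * (a == b))
    })
  }
}

#' Precision of the top-L ranked candidates
#'
#' The fraction of the \code{L} top-ranked candidate pairs that are probe
#' links, \eqn{L_r / L}. The ranking's deterministic tie order (descending
#' score, then lexicographic pair label) makes the value reproducible.
#'
#' @inheritParams auc_score
#' @param L Ranking depth; default 100.
#' @return Precision in [0, 1].
#' @export
precision_at <- function(split, scored, L = 100L) {
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (L > nrow(scored)) {
    stop("L = ", L, " exceeds the ", nrow(scored), " candidate pairs",
         call. = FALSE)
  }
  pos <- probe_positions(split, scored)
  sum(pos <= L) / L
}

#' Run a repeated train/probe link-prediction experiment
#'
#' For each run: split the links, fit the index on the training graph, rank
#' all candidate pairs, and measure AUC and precision at \code{L}. Per-run
#' seeds are derived deterministically from the master seed, so the whole
#' experiment is reproducible.
#'
#' @param net An undirected simple \code{igraph} graph.
#' @param index Index name, see [link_model()].
#' @param runs Number of independent splits; default 100, matching the usual
#'   reporting convention.
#' @param probe_fraction Fraction of links hidden per run; default 0.1.
#' @param L Precision depth; default 100 (use a smaller L on graphs with few
#'   candidate pairs).
#' @param auc_mode \code{"exact"} or \code{"sampled"}.
#' @param auc_n Comparisons per run for sampled AUC.
#' @param seed Master seed.
#' @return An object of class \code{"link_experiment"}: per-run results plus
#'   mean and standard deviation of both metrics.
#' @examples
#' g <- erdos_renyi(60, 0.15, seed = 1)
#' run_experiment(g, "MI", runs = 3, L = 10, seed = 1)
#' @export
run_experiment <- function(net, index = "MI", runs = 100L,
                           probe_fraction = 0.1, L = 100L,
                           auc_mode = c("exact", "sampled"), auc_n = NULL,
                           seed = NULL) {
  auc_mode <- match.arg(auc_mode)
  if (runs < 1L) stop("runs must be >= 1", call. = FALSE)
  # headroom below 2^31 so the derived per-stage offsets stay valid integers
  run_seeds <- with_seed(seed, sample.int(2147483000L, runs))
  res <- lapply(seq_len(runs), function(r) {
    sp <- split_train_probe(net, probe_fraction, seed = run_seeds[r])
    scored <- with_seed(run_seeds[r] + 1L,  # only the random index draws
                        rank_candidates(sp$train, index))
    data.frame(run = r, seed = run_seeds[r],
               auc = auc_score(sp, scored, auc_mode, n = auc_n,
                               seed = run_seeds[r] + 2L),
               precision = precision_at(sp, scored, L))
  })
  runs_df <- do.call(rbind, res)
  out <- list(index = toupper(index), runs = runs_df,
              probe_fraction = probe_fraction, L = L,
              auc_mode = auc_mode, auc_n = auc_n, seed = seed,
              auc_mean = mean(runs_df$auc), auc_sd = stats::sd(runs_df$auc),
              precision_mean = mean(runs_df$precision),
              precision_sd = stats::sd(runs_df$precision))
  class(out) <- "link_experiment"
  out
}

#' @export
print.link_experiment <- function(x, digits = 4, ...) {
  cat("Link-prediction experiment:", x$index, "index,",
      nrow(x$runs), "runs, probe fraction", x$probe_fraction, "\n")
  cat("  AUC      :", round(x$auc_mean, digits), "+/-",
      round(x$auc_sd, digits), paste0("(", x$auc_mode, ")"), "\n")
  cat("  precision:", round(x$precision_mean, digits), "+/-",
      round(x$precision_sd, digits), paste0("(top-", x$L, ")"), "\n")
  invisible(x)
}

#' Serialise an experiment report as CSV
#'
#' One row per run (\code{run, seed, auc, precision}) followed by a summary
#' row holding the means; machine-readable and diff-stable.
#'
#' @param report A \code{"link_experiment"} object.
#' @param con A file path or writable connection.
#' @export
write_eval_report <- function(report, con) {
  df <- report$runs
  df$run <- as.character(df$run)
  df <- rbind(df, data.frame(run = "mean", seed = NA,
                             auc = report$auc_mean,
                             precision = report$precision_mean))
  utils::write.csv(df, con, row.names = FALSE)
}
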