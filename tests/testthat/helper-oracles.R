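# Independent brute-force transcriptions of the scoring formulas, written
# directly from the definitions and sharing no code with the package
# internals (igraph is used only for adjacency queries). These are the
# oracles all index implementations are checked against.

o_neigh <- function(g, v) as.integer(igraph::neighbors(g, v))

o_prior <- function(kx, ky, M) choose(M - kx, ky) / choose(M, ky)

o_selfinfo <- function(kx, ky, M) -log2(1 - o_prior(kx, ky, M))

# triad / open neighbour-pair counts by explicit enumeration
o_counts <- function(g, z) {
  nb <- o_neigh(g, z)
  tri <- 0L; open <- 0L
  if (length(nb) >= 2) {
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b) {
        if (igraph::are_adjacent(g, nb[a], nb[b])) tri <- tri + 1L
        else open <- open + 1L
      }
    }
  }
  c(tri, open)
}

# average mutual information of z, with the C_z = 0 / degree < 2 stipulation
o_iz <- function(g, z) {
  nb <- o_neigh(g, z)
  if (length(nb) < 2) return(0)
  deg <- igraph::degree(g); M <- igraph::ecount(g)
  cnt <- o_counts(g, z)
  cz <- cnt[1] / sum(cnt)
  if (cz == 0) return(0)
  prs <- utils::combn(nb, 2)
  mean(apply(prs, 2, function(p)
    o_selfinfo(deg[p[1]], deg[p[2]], M) - (-log2(cz))))
}

o_mi <- function(g, x, y) {
  deg <- igraph::degree(g); M <- igraph::ecount(g)
  cn <- intersect(o_neigh(g, x), o_neigh(g, y))
  s <- 0
  for (z in cn) s <- s + o_iz(g, z)
  s - o_selfinfo(deg[x], deg[y], M)
}

o_cn <- function(g, x, y) length(intersect(o_neigh(g, x), o_neigh(g, y)))

o_ra <- function(g, x, y) {
  cn <- intersect(o_neigh(g, x), o_neigh(g, y))
  sum(1 / igraph::degree(g)[cn])
}

o_lnb_s <- function(g) {
  n <- igraph::vcount(g); M <- igraph::ecount(g)
  (n * (n - 1) / 2 - M) / M
}

o_lnb_r <- function(g, z) {
  cnt <- o_counts(g, z)
  (cnt[1] + 1) / (cnt[2] + 1)
}

o_lnb_cn <- function(g, x, y) {
  cn <- intersect(o_neigh(g, x), o_neigh(g, y))
  s <- o_lnb_s(g)
  out <- 0
  for (z in cn) out <- out + log2(s * o_lnb_r(g, z))
  out
}

o_lnb_ra <- function(g, x, y) {
  cn <- intersect(o_neigh(g, x), o_neigh(g, y))
  s <- o_lnb_s(g)
  deg <- igraph::degree(g)
  out <- 0
  for (z in cn) out <- out + log2(s * o_lnb_r(g, z)) / deg[[z]]
  out
}

o_car <- function(g, x, y) {
  cn <- intersect(o_neigh(g, x), o_neigh(g, y))
  links <- 0
  for (z in cn) links <- links + length(intersect(o_neigh(g, z), cn))
  length(cn) * links / 2
}

o_cra <- function(g, x, y) {
  cn <- intersect(o_neigh(g, x), o_neigh(g, y))
  out <- 0
  for (z in cn) out <- out + length(intersect(o_neigh(g, z), cn)) / igraph::degree(g)[z]
  out
}

# AUC by the literal double loop over every probe x non-existent comparison
o_auc <- function(s_probe, s_none) {
  n_better <- 0; n_tie <- 0
  for (a in s_probe) for (b in s_none) {
    if (a > b) n_better <- n_better + 1
    else if (a == b) n_tie <- n_tie + 1
  }
  (n_better + 0.5 * n_tie) / (length(s_probe) * length(s_none))
}

# all-pairs shortest distances by a hand-rolled BFS (netstats oracle)
o_distances <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) o_neigh(g, v))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- lvl
      frontier <- nxt
    }
  }
  d
}

# score every candidate pair of `g` with each oracle; returns keyed vectors
oracle_all_scores <- function(g, fun) {
  n <- igraph::vcount(g)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (!igraph::are_adjacent(g, i, j)) {
      out[pair_key_test(g, i, j)] <- fun(g, i, j)
    }
  }
  out
}

pair_key_test <- function(g, i, j) {
  labs <- igraph::V(g)$name
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(g)))
  paste(min(labs[i], labs[j]), max(labs[i], labs[j]), sep = "\t")
}

ranked_as_keyed <- function(ranked) {
  stats::setNames(ranked$score,
                  paste(ranked$node1, ranked$node2, sep = "\t"))
}

# non-adjacent node-index pairs of a graph, by direct enumeration
candidate_pairs_for_test <- function(g) {
  n <- igraph::vcount(g)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (!igraph::are_adjacent(g, i, j)) out <- rbind(out, c(i, j))
  }
  out
}

# small random test graph via the package generator (generation itself is
# tested separately; here it only supplies topologies)
random_graph <- function(n, p, seed) milink::erdos_renyi(n, p, seed)
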