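test_that("train/probe splitting partitions the links reproducibly", {
  g <- erdos_renyi(60, 0.1, seed = 8)
  M <- igraph::ecount(g)
  sp <- split_train_probe(g, 0.1, seed = 42)
  expect_equal(nrow(sp$probe), round(0.1 * M))
  expect_equal(igraph::ecount(sp$train), M - round(0.1 * M))
  # all nodes are kept, even if their training degree drops to 0
  expect_equal(igraph::vcount(sp$train), igraph::vcount(g))

  sp2 <- split_train_probe(g, 0.1, seed = 42)
  expect_identical(sp$probe, sp2$probe)

  expect_error(split_train_probe(g, 0), "probe_fraction")
  expect_error(split_train_probe(g, 1.2), "probe_fraction")
})

test_that("train plus probe reassembles the original edge set", {
  for (seed in 1:8) {
    g <- random_graph(25, 0.2, seed)
    sp <- split_train_probe(g, 0.25, seed = seed)
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    train_keys <- key(igraph::as_edgelist(sp$train))
    probe_keys <- key(sp$probe)
    expect_length(intersect(train_keys, probe_keys), 0)
    expect_identical(sort(c(train_keys, probe_keys)),
                     key(igraph::as_edgelist(g)))
  }
})

test_that("rank_candidates covers the candidate universe in stable order", {
  p3 <- fixture_graph("path3")
  r <- rank_candidates(p3, "CN")
  expect_identical(r$node1[1], "a")  # (a, c) is the sole pair with a CN
  expect_identical(r$node2[1], "c")

  g <- random_graph(15, 0.2, 3)
  r <- rank_candidates(g, "MI")
  expect_equal(nrow(r), nrow(candidate_pairs_for_test(g)))
  expect_true(all(diff(r$score) <= 1e-15))
  # deterministic lexicographic order inside exact-tie blocks
  ties <- split(seq_len(nrow(r)), match(r$score, unique(r$score)))
  for (blk in ties) {
    labs <- paste(r$node1[blk], r$node2[blk])
    expect_identical(labs, sort(labs))
  }
  expect_error(rank_candidates(g, "katz"), "unknown index")
})

test_that("AUC handles the boundary cases of the comparison formula", {
  g <- erdos_renyi(40, 0.15, seed = 5)
  sp <- split_train_probe(g, 0.2, seed = 5)
  scored <- rank_candidates(sp$train, "CN")

  # all scores identical: every comparison is a tie
  flat <- scored; flat$score <- rep(1, nrow(flat))
  expect_equal(auc_score(sp, flat), 0.5)

  # perfect separation: probe pairs above everything else
  keys <- paste(scored$node1, scored$node2, sep = "\t")
  pk <- paste(pmin(sp$probe[, 1], sp$probe[, 2]),
              pmax(sp$probe[, 1], sp$probe[, 2]), sep = "\t")
  perfect <- scored; perfect$score <- ifelse(keys %in% pk, 2, 1)
  expect_equal(auc_score(sp, perfect), 1)
})

test_that("exact AUC equals the brute-force double loop", {
  for (seed in 1:6) {
    g <- random_graph(30, 0.15, seed)
    sp <- split_train_probe(g, 0.2, seed = seed + 100)
    for (idx in c("MI", "CN", "RA")) {
      scored <- rank_candidates(sp$train, idx)
      keys <- paste(scored$node1, scored$node2, sep = "\t")
      pk <- paste(pmin(sp$probe[, 1], sp$probe[, 2]),
                  pmax(sp$probe[, 1], sp$probe[, 2]), sep = "\t")
      is_probe <- keys %in% pk
      expect_equal(auc_score(sp, scored),
                   o_auc(scored$score[is_probe], scored$score[!is_probe]),
                   tolerance = 1e-12, label = paste(idx, seed))
    }
  }
})

test_that("sampled AUC converges to the exact value", {
  g <- erdos_renyi(80, 0.08, seed = 12)
  sp <- split_train_probe(g, 0.1, seed = 12)
  scored <- rank_candidates(sp$train, "RA")
  exact <- auc_score(sp, scored)
  sampled <- auc_score(sp, scored, mode = "sampled", n = 1e5, seed = 99)
  expect_lt(abs(sampled - exact), 0.01)
  expect_error(auc_score(sp, scored, mode = "sampled"), "requires n")
})

test_that("AUC and precision are invariant under monotone score transforms", {
  g <- erdos_renyi(40, 0.12, seed = 21)
  sp <- split_train_probe(g, 0.2, seed = 21)
  scored <- rank_candidates(sp$train, "RA")
  warped <- scored
  warped$score <- exp(3 * warped$score) - 0.5
  expect_equal(auc_score(sp, warped), auc_score(sp, scored), tolerance = 1e-12)
  expect_equal(precision_at(sp, warped, 10), precision_at(sp, scored, 10))
})

test_that("precision@L counts probe hits in the top of the ranking", {
  g <- erdos_renyi(40, 0.15, seed = 5)
  sp <- split_train_probe(g, 0.2, seed = 5)
  scored <- rank_candidates(sp$train, "CN")
  keys <- paste(scored$node1, scored$node2, sep = "\t")
  pk <- paste(pmin(sp$probe[, 1], sp$probe[, 2]),
              pmax(sp$probe[, 1], sp$probe[, 2]), sep = "\t")

  # force the probe pairs to the very top: precision 1
  rigged <- scored
  rigged$score <- ifelse(keys %in% pk, 2, 1)
  rigged <- rigged[order(-rigged$score, rigged$node1, rigged$node2), ]
  expect_equal(precision_at(sp, rigged, nrow(sp$probe)), 1)

  # and to the very bottom: precision 0
  rigged$score <- ifelse(keys %in% pk, -1, 1)
  rigged <- rigged[order(-rigged$score, rigged$node1, rigged$node2), ]
  expect_equal(precision_at(sp, rigged, 10), 0)

  expect_error(precision_at(sp, scored, nrow(scored) + 1), "exceeds")
})

test_that("run_experiment is reproducible and reduces to one round", {
  g <- erdos_renyi(50, 0.12, seed = 77)
  r1 <- run_experiment(g, "RA", runs = 1, L = 10, seed = 7)
  sp <- split_train_probe(g, 0.1, seed = r1$runs$seed[1])
  scored <- rank_candidates(sp$train, "RA")
  expect_equal(r1$auc_mean, auc_score(sp, scored), tolerance = 1e-12)
  expect_equal(r1$precision_mean, precision_at(sp, scored, 10))

  r2 <- run_experiment(g, "MI", runs = 4, L = 10, seed = 31)
  r3 <- run_experiment(g, "MI", runs = 4, L = 10, seed = 31)
  expect_identical(r2$runs, r3$runs)
  expect_equal(r2$auc_mean, mean(r2$runs$auc))

  f <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(r2, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 5)  # 4 runs + summary row
  expect_equal(df$auc[5], r2$auc_mean)
})

test_that("a random-score index sits at chance level", {
  g <- erdos_renyi(120, 0.08, seed = 9)
  r <- run_experiment(g, "random", runs = 10, L = 20,
                      auc_mode = "sampled", auc_n = 2e4, seed = 15)
  expect_lt(abs(r$auc_mean - 0.5), 3 * max(r$auc_sd / sqrt(10), 0.005))
})
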