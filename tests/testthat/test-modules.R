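test_that("Barber modularity: trivial partitions score zero, blocks score 0.5", {
  net <- two_block_network()
  nodes <- c(net$genome_ids, net$family_ids)
  expect_equal(barber_modularity(net, stats::setNames(rep(1, 8), nodes)), 0)
  expect_equal(barber_modularity(net, stats::setNames(1:8, nodes)), 0)
  blocks <- stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2), nodes)
  expect_equal(barber_modularity(net, blocks), 0.5)
  expect_error(barber_modularity(net, stats::setNames(1, "g1")), "label")
})

test_that("annealing finds the known optimum and is seed-deterministic", {
  net <- two_block_network()
  hits <- vapply(1:20, function(s) anneal_partition(net, seed = s)$Q, 0)
  expect_gte(sum(hits == 0.5), 19)
  p1 <- anneal_partition(net, seed = 42)
  p2 <- anneal_partition(net, seed = 42)
  expect_identical(p1$labels, p2$labels)
  # single edge: both nodes end up together, Q = 0
  single <- gs_from_pairs(g1 = "f1")
  ps <- anneal_partition(build_bipartite_network(single), seed = 1)
  expect_equal(ps$Q, 0)
  expect_equal(ps$n_modules, 1)
  expect_error(anneal_partition(net, 1, anneal_schedule(cooling = 1.2)),
               "cooling")
})

test_that("SA reported Q matches the exact evaluation and beats all-in-one", {
  set.seed(31)
  for (i in 1:5) {
    net <- random_bipartite(6, 8, p = 0.4)
    p <- anneal_partition(net, seed = i)
    expect_equal(p$Q, barber_modularity(net, p), tolerance = 1e-9)
    expect_gte(p$Q, 0)
  }
})

test_that("exhaustive search certifies SA on small graphs", {
  set.seed(32)
  for (i in 1:5) {
    net <- random_bipartite(sample(2:4, 1), sample(2:4, 1))
    ex <- best_partition_exhaustive(net)
    sa <- max(vapply(1:3, function(s) anneal_partition(net, seed = s)$Q, 0))
    expect_equal(sa, ex$Q, tolerance = 1e-9)
  }
})

test_that("replicate ensembles pick the best partition deterministically", {
  net <- two_block_network()
  ens <- detect_modules(net, n_replicates = 10, seed = 5)
  expect_equal(ens$best$Q, 0.5)
  expect_equal(ens$best_index, which.max(vapply(ens$replicates,
                                                function(p) p$Q, 0)))
  # identical master seed reproduces the whole ensemble
  ens2 <- detect_modules(net, n_replicates = 10, seed = 5)
  expect_identical(lapply(ens$replicates, `[[`, "labels"),
                   lapply(ens2$replicates, `[[`, "labels"))
  # deterministic toy: all replicates identical, robustness 1
  expect_true(all(ens$robustness$robustness_genomes == 1))
  expect_true(all(ens$robustness$robustness_genes == 1))
  # one replicate: trivially robustness 1
  e1 <- detect_modules(net, n_replicates = 1, seed = 9)
  expect_true(all(e1$robustness$robustness_genomes == 1))
})

test_that("robustness and cross-similarity count co-assignments correctly", {
  net <- two_block_network()
  nodes <- c(net$genome_ids, net$family_ids)
  blocks <- stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2), nodes)
  merged <- stats::setNames(rep(1, 8), nodes)
  mk <- function(lab) vironet:::new_partition(lab, net)
  # modules merged in exactly 2 of 4 replicates: cross-similarity 0.5
  ens <- structure(list(
    replicates = list(mk(blocks), mk(blocks), mk(merged), mk(merged)),
    best_index = 1L, best = mk(blocks),
    co_genome = vironet:::co_assignment(list(mk(blocks), mk(blocks),
                                             mk(merged), mk(merged)),
                                        net$genome_ids),
    co_family = vironet:::co_assignment(list(mk(blocks), mk(blocks),
                                             mk(merged), mk(merged)),
                                        net$family_ids),
    network = net), class = "partition_ensemble")
  rb <- robustness_matrices(ens)
  expect_true(all(rb$robustness$robustness_genomes == 1))
  expect_equal(rb$cross_similarity["1", "2"], 0.5)

  # half of one module defects in every replicate: hand-counted robustness
  defect <- blocks
  defect["g2"] <- 3
  ens2 <- structure(list(
    replicates = list(mk(blocks), mk(defect)), best_index = 1L,
    best = mk(blocks),
    co_genome = vironet:::co_assignment(list(mk(blocks), mk(defect)),
                                        net$genome_ids),
    co_family = vironet:::co_assignment(list(mk(blocks), mk(defect)),
                                        net$family_ids),
    network = net), class = "partition_ensemble")
  rb2 <- robustness_matrices(ens2)
  # module 1 = {g1, g2}: the only pair co-assigned in 1 of 2 replicates
  expect_equal(rb2$robustness$robustness_genomes[
    rb2$robustness$module == "1"], 0.5)
})

test_that("degree-preserving null keeps every degree and changes edges", {
  set.seed(33)
  net <- random_bipartite(10, 15, p = 0.3)
  d0 <- igraph::degree(net$graph)
  rn <- rewire_bipartite(net, seed = 7)
  d1 <- igraph::degree(rn$graph)
  expect_equal(d1[names(d0)], d0)
  expect_false(identical(network_edges(rn), network_edges(net)))
  expect_error(rewire_bipartite(build_bipartite_network(
    gs_from_pairs(g1 = "f1")), seed = 1), "small")
})

test_that("planted modular structure is significant, add-one p never zero", {
  pl <- generate_planted_network(planted_config(seed = 41))
  net <- build_bipartite_network(pl$genomes)
  ens <- detect_modules(net, n_replicates = 3, seed = 42)
  sig <- partition_significance(net, ens$best$Q, n_null = 30, seed = 43)
  expect_lte(sig$p_value, 1 / 31)
  expect_gt(sig$p_value, 0)
  expect_error(partition_significance(net, Inf, n_null = 5, seed = 1),
               "finite")
})

test_that("degree-matched random networks are not called modular", {
  set.seed(44)
  net <- random_bipartite(12, 18, p = 0.25)
  rnd <- rewire_bipartite(net, seed = 45)       # a genuine null draw
  ens <- detect_modules(rnd, n_replicates = 5, seed = 46)
  sig <- partition_significance(rnd, ens$best$Q, n_null = 30, seed = 47,
                                n_replicates_null = 5)
  expect_gte(sig$p_value, 0.1)
})
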