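test_that("pangenome merging follows the min-denominator single-linkage rule", {
  # two identical genomes collapse to one pangenome
  gs <- gs_from_pairs(g1 = c("a", "b", "c"), g2 = c("a", "b", "c"))
  m <- merge_redundant_genomes(gs)
  expect_equal(n_genomes(m), 1)
  expect_setequal(family_sets(m)[[1]], c("a", "b", "c"))

  # 95% shared -> merged; 50% shared -> kept separate
  fams <- sprintf("f%02d", 1:20)
  gs2 <- gs_from_pairs(g1 = fams, g2 = c(fams[1:19], "x1"),
                       g3 = c(fams[1:10], sprintf("y%d", 1:10)))
  m2 <- merge_redundant_genomes(gs2)
  expect_equal(n_genomes(m2), 2)
  expect_true("g3" %in% m2$genomes$genome_id)

  # chain A~B (0.95), B~C (0.95), A~C (0.6): all merged via single linkage
  A <- c(sprintf("x%02d", 1:20), sprintf("z%02d", 1:10))
  B <- c(sprintf("x%02d", 1:19), "y1")
  C <- c(sprintf("x%02d", 2:19), "y1", sprintf("w%02d", 1:11))
  gs3 <- gs_from_pairs(A = A, B = B, C = C)
  expect_equal(length(intersect(A, B)) / 20, 0.95)
  expect_equal(length(intersect(B, C)) / 20, 0.95)
  expect_equal(length(intersect(A, C)) / 30, 0.6)
  m3 <- merge_redundant_genomes(gs3)
  expect_equal(n_genomes(m3), 1)
  expect_setequal(strsplit(m3$genomes$members, ",")[[1]], c("A", "B", "C"))
})

test_that("merging is idempotent", {
  set.seed(1)
  pl <- generate_planted_network(planted_config(seed = 10))
  m1 <- merge_redundant_genomes(pl$genomes)
  m2 <- merge_redundant_genomes(m1)
  expect_equal(n_genomes(m2), n_genomes(m1))
  expect_equal(sort(m2$membership$family_id), sort(m1$membership$family_id))
})

test_that("bipartite network construction and giant component", {
  # 3 genomes sharing one family: a star
  gs <- gs_from_pairs(g1 = "f", g2 = "f", g3 = "f")
  net <- build_bipartite_network(gs)
  expect_equal(length(net$genome_ids), 3)
  expect_equal(length(net$family_ids), 1)
  expect_equal(igraph::ecount(net$graph), 3)

  # isolated pair drops under giant_only
  gs2 <- gs_from_pairs(g1 = c("f", "a"), g2 = "f", g3 = "f", g4 = "f",
                       p1 = "q", p2 = "q")
  net2 <- build_bipartite_network(gs2, giant_only = TRUE)
  expect_setequal(net2$dropped, c("p1", "p2", "q"))
  net2f <- build_bipartite_network(gs2, giant_only = FALSE)
  expect_equal(igraph::vcount(net2f$graph), 6 + 3)
  expect_equal(igraph::ecount(net2f$graph), 7)
})

test_that("edge count equals both degree sums", {
  set.seed(2)
  net <- random_bipartite(8, 12)
  deg <- igraph::degree(net$graph)
  expect_equal(sum(deg[net$genome_ids]), igraph::ecount(net$graph))
  expect_equal(sum(deg[net$family_ids]), igraph::ecount(net$graph))
})

test_that("core restriction removes non-core families and empty genomes", {
  gs <- gs_from_pairs(g1 = c("c1", "c2", "n1"), g2 = c("c1", "n2"),
                      g3 = c("c2", "c3"), g4 = c("c3", "n1"),
                      g5 = c("n1", "n2"))
  net <- build_bipartite_network(gs, giant_only = FALSE)
  core <- c("c1", "c2", "c3")
  rnet <- restrict_to_core(net, core)
  expect_setequal(rnet$family_ids, core)
  expect_setequal(rnet$genome_ids, c("g1", "g2", "g3", "g4"))  # g5 dropped
  expect_equal(igraph::ecount(rnet$graph), 6)
  # restriction never increases a degree
  d0 <- igraph::degree(net$graph)
  d1 <- igraph::degree(rnet$graph)
  expect_true(all(d1 <= d0[names(d1)]))
  # identity when all families are core
  rid <- restrict_to_core(net, net$family_ids)
  expect_equal(igraph::ecount(rid$graph), igraph::ecount(net$graph))
  expect_error(restrict_to_core(net, "nope"), "core")
})

test_that("degree statistics on complete bipartite and degenerate graphs", {
  gs <- gs_from_pairs(g1 = paste0("f", 1:3), g2 = paste0("f", 1:3),
                      g3 = paste0("f", 1:3), g4 = paste0("f", 1:3))
  prof <- degree_statistics(build_bipartite_network(gs))
  expect_true(all(prof$genome_degrees == 3))
  expect_true(all(prof$family_degrees == 4))
  expect_true(is.na(prof$gamma))  # all-equal degrees: exponent undefined

  single <- gs_from_pairs(g1 = "f1")
  p2 <- degree_statistics(build_bipartite_network(single))
  expect_equal(unname(p2$genome_degrees), 1)
  expect_equal(unname(p2$family_degrees), 1)
})

test_that("power-law ML recovers planted exponents within 0.1 at 1e4 samples", {
  K <- 1:10^6
  for (g in c(1.8, 2.0, 2.5)) {
    set.seed(round(g * 100))
    p <- K^(-g)
    k <- findInterval(stats::runif(1e4), cumsum(p / sum(p))) + 1L
    expect_lt(abs(fit_power_exponent(k) - g), 0.1)
  }
  expect_error(fit_power_exponent(rep(3, 10)), "degenerate")
})

test_that("bipartite clustering coefficients match hand calculations", {
  # complete bipartite K_{2,2}: all coefficients 1
  gs <- gs_from_pairs(g1 = c("f1", "f2"), g2 = c("f1", "f2"))
  cp <- clustering_profile(build_bipartite_network(gs))
  expect_true(all(cp$coefficients == 1))

  # path g1-f1-g2-f2-g3: coefficient of f1 is 1/3
  gsp <- gs_from_pairs(g1 = "f1", g2 = c("f1", "f2"), g3 = "f2")
  cpp <- clustering_profile(build_bipartite_network(gsp))
  expect_equal(unname(cpp$coefficients["f1"]), 1 / 3)

  # isolated edge: undefined for both nodes
  gse <- gs_from_pairs(g1 = "f1")
  cpe <- clustering_profile(build_bipartite_network(gse))
  expect_true(all(is.na(cpe$coefficients)))
})

test_that("network summary density matches the counts identity", {
  set.seed(3)
  net <- random_bipartite(6, 9)
  s <- network_summary(net)
  expect_equal(s$edge_density, s$edges / (s$genomes * s$families))
  expect_equal(s$mean_genes_per_genome, s$edges / s$genomes)
})
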