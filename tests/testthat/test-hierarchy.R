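test_that("connector identification applies the exp(-1) threshold per module", {
  # 2 modules x 2 genomes, equal weights
  gs <- gs_from_pairs(a1 = c("both", "high_a", "onlyA"),
                      a2 = c("both", "high_a"),
                      b1 = c("both", "low_b"),
                      b2 = c("both", "high_a"))
  w <- equal_weights(gs)
  part <- stats::setNames(c(1, 1, 2, 2), c("a1", "a2", "b1", "b2"))
  con <- identify_connectors(part, gs, w)
  tab <- con$table
  # prevalence 1.0 in both modules -> connector
  expect_true(tab$connector[tab$family_id == "both"])
  # prevalence 1 in module 1 but 0.5 in module 2: both above exp(-1)
  expect_true(tab$connector[tab$family_id == "high_a"])
  # 0.5 and 0.5 -> connector (both exceed 0.3679); 0.5 in one only -> kept,
  # not a connector
  expect_false(tab$connector[tab$family_id == "low_b"])
  expect_equal(tab$n_qualifying[tab$family_id == "low_b"], 1L)
  # 0.30 in the second module stays below the threshold
  expect_equal(con$prevalence["onlyA", "2"], 0)
  expect_false(tab$connector[tab$family_id == "onlyA"])
})

test_that("prevalence 0.30 does not qualify but 0.40 does", {
  # module of 10 genomes: family in 3 -> 0.30 < exp(-1); in 4 -> 0.40 >
  gs <- gs_from_pairs(
    m1 = "f", m2 = "f", m3 = "f", m4 = "anchor", m5 = "anchor",
    m6 = "anchor", m7 = "anchor", m8 = "anchor", m9 = "anchor", m10 = "anchor")
  w <- equal_weights(gs)
  part <- stats::setNames(rep(1, 10), paste0("m", 1:10))
  con <- identify_connectors(part, gs, w)
  expect_equal(con$prevalence["f", "1"], 0.3)
  expect_equal(con$table$n_qualifying[con$table$family_id == "f"], 0L)
})

test_that("module network construction keeps single-module families", {
  prev <- matrix(c(1, 1, 1, 1, 1, 1, 0.9, 0, 0, 0, 0, 0), nrow = 6,
                 dimnames = list(c(paste0("c", 1:3), "s1", "x1", "x2"),
                                 c("1", "2")))
  prev["x1", ] <- c(0.5, 0.6)
  prev["x2", ] <- c(0.1, 0.2)
  con <- structure(list(prevalence = prev, threshold = exp(-1)),
                   class = "connector_table")
  mn <- build_module_network(con)
  expect_setequal(mn$genome_ids, c("M1", "M2"))
  # x2 never qualifies and is absent; s1 qualifies once, degree 1
  expect_false("x2" %in% mn$family_ids)
  deg <- igraph::degree(mn$graph)
  expect_equal(unname(deg["s1"]), 1)
  expect_equal(unname(deg["c1"]), 2)
  con0 <- structure(list(prevalence = prev * 0, threshold = exp(-1)),
                    class = "connector_table")
  expect_error(build_module_network(con0), "no family qualifies")
})

test_that("planted supermodules merge at iteration 1 with robustness 1", {
  cfg <- planted_config(n_supermodules = 2, modules_per_supermodule = 3,
                        genomes_per_module = 10, n_signature_per_module = 0,
                        p_signature = 0.3, n_connector_per_module_pair = 0,
                        n_hallmark_per_supermodule = 6, p_hallmark = 1,
                        n_orfans_per_genome = 2, n_noise_families = 0,
                        seed = 51, strong_signal = FALSE)
  pl <- generate_planted_network(cfg)
  w <- suppressMessages(genome_weights(distance_matrix(pl$genomes)))
  truth_part <- pl$truth$genome_module[pl$genomes$genomes$genome_id]
  # n_null = 100 so the smallest attainable p (1/101) clears the 0.01 gate
  h <- detect_supermodules(truth_part, pl$genomes, w, n_replicates = 50,
                           seed = 52, n_null = 100)
  sm <- h$nodes[h$nodes$type == "supermodule", ]
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$iteration == 1))
  expect_true(all(sm$robustness == 1))
  expect_equal(length(h$supermodules), 2)
  # recovered supermodules match the planted ones
  truth_sm <- split(names(pl$truth$genome_supermodule),
                    pl$truth$genome_supermodule)
  canon <- function(groups) {
    g <- lapply(groups, sort)
    unname(g[order(vapply(g, `[`, "", 1L))])
  }
  expect_equal(canon(h$supermodules), canon(truth_sm))
  # newick rendering covers all leaves
  nwk <- hierarchy_newick(h)
  expect_length(nwk, 2)
  expect_true(all(grepl("^\\(", nwk)))
})

test_that("no cross-module glue yields a flat hierarchy", {
  cfg <- planted_config(n_supermodules = 2, modules_per_supermodule = 3,
                        genomes_per_module = 10, n_signature_per_module = 10,
                        p_signature = 0.9, n_connector_per_module_pair = 0,
                        n_hallmark_per_supermodule = 0,
                        n_orfans_per_genome = 2, n_noise_families = 0,
                        seed = 53, strong_signal = FALSE)
  pl <- generate_planted_network(cfg)
  w <- suppressMessages(genome_weights(distance_matrix(pl$genomes)))
  truth_part <- pl$truth$genome_module[pl$genomes$genomes$genome_id]
  h <- detect_supermodules(truth_part, pl$genomes, w, n_replicates = 50,
                           seed = 54, n_null = 50)
  expect_equal(n_merges(h), 0)
  expect_equal(length(h$supermodules), 6)
})

test_that("dissection restricted to all modules reproduces the primary run", {
  pl <- generate_planted_network(planted_config(seed = 55))
  net <- build_bipartite_network(pl$genomes)
  ens <- detect_modules(net, n_replicates = 2, seed = 56)
  mods <- unique(ens$best$labels[net$genome_ids])
  sub <- dissect_subnetwork(net, mods, ens$best, n_replicates = 2, seed = 56)
  expect_equal(sub$best$Q, ens$best$Q, tolerance = 1e-9)
  expect_error(dissect_subnetwork(net, c(998, 999), ens$best), "not present")
})

test_that("dissection resolves nested submodules hidden at full scale", {
  # one broad module with two exclusive signature sets, embedded next to a
  # dominant module; at full scale the small split may be unresolved, the
  # dissected subnetwork separates the two halves
  mk <- function(g, f) data.frame(genome_id = g, family_id = f, copy_count = 1L)
  rows <- list()
  for (i in 1:6) rows[[length(rows) + 1]] <- mk(paste0("a", i), paste0("sa", 1:8))
  for (i in 1:6) rows[[length(rows) + 1]] <- mk(paste0("b", i), paste0("sb", 1:8))
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- mk(paste0("a", i), "shared")
    rows[[length(rows) + 1]] <- mk(paste0("b", i), "shared")
  }
  gs <- genome_set(do.call(rbind, rows))
  net <- build_bipartite_network(gs)
  part <- stats::setNames(rep(1, igraph::vcount(net$graph)),
                          c(net$genome_ids, net$family_ids))
  sub <- dissect_subnetwork(net, 1, vironet:::new_partition(part, net),
                            n_replicates = 5, seed = 57)
  glab <- sub$best$labels[sub$network$genome_ids]
  a_lab <- unique(glab[paste0("a", 1:6)])
  b_lab <- unique(glab[paste0("b", 1:6)])
  expect_length(a_lab, 1)
  expect_length(b_lab, 1)
  expect_false(a_lab == b_lab)
})
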