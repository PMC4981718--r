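test_that("normalized MI matches hand-evaluated closed forms", {
  # perfect match: gene coextensive with a module of weight 0.25
  expect_equal(vironet:::nmi_cells(0.25, 0, 0, 0.75), 1, tolerance = 1e-12)
  # exact independence
  expect_equal(vironet:::nmi_cells(0.125, 0.375, 0.125, 0.375), 0,
               tolerance = 1e-12)
  # module weight 0.5, gene in half of it: frozen hand evaluation
  # MI = 0.25 log2(0.25/(0.25*0.5)) + 0.5 log2(0.5/(0.75*0.5)) = 0.4575188
  # H  = 1.5  ->  0.3050125
  expect_equal(vironet:::nmi_cells(0.25, 0, 0.25, 0.5), 0.30501249, # nolint
               tolerance = 1e-7)
  # degenerate single-cell mass
  expect_equal(vironet:::nmi_cells(1, 0, 0, 0), 0)
})

test_that("normalized_mutual_information wires weights and patterns", {
  gs <- gs_from_pairs(g1 = c("s", "bg"), g2 = c("s", "bg"),
                      g3 = "bg", g4 = "bg", g5 = "bg", g6 = "bg",
                      g7 = "bg", g8 = "bg")
  w <- equal_weights(gs)
  # gene exactly coextensive with module {g1, g2}
  expect_equal(normalized_mutual_information("s", c("g1", "g2"), gs, w), 1,
               tolerance = 1e-12)
  # background gene present everywhere is independent of any module
  expect_equal(normalized_mutual_information("bg", c("g1", "g2"), gs, w), 0,
               tolerance = 1e-12)
  # mi_matrix agrees with the scalar version
  groups <- list(A = c("g1", "g2"), B = paste0("g", 3:8))
  mi <- mi_matrix(gs, w, groups)
  expect_equal(mi["s", "A"],
               normalized_mutual_information("s", groups$A, gs, w))
})

test_that("signature thresholds are applied to best and second-best MI", {
  mi <- rbind(sig = c(0.7, 0.01), mid = c(0.5, 0.001), leak = c(0.8, 0.05),
              perfect = c(1, 0))
  colnames(mi) <- c("m1", "m2")
  sg <- classify_signature(mi)
  expect_true(sg$signature[sg$family_id == "sig"])
  expect_true(sg$signature[sg$family_id == "perfect"])
  expect_false(sg$signature[sg$family_id == "mid"])   # best 0.5 fails
  expect_false(sg$signature[sg$family_id == "leak"])  # second 0.05 fails
  # single-module partition: second-best MI defined as 0
  sg1 <- classify_signature(mi[, 1, drop = FALSE])
  expect_true(all(sg1$mi_second == 0))
})

test_that("hallmark calls require connector status and 0.35 prevalence", {
  # 2 supermodules of 2 modules x 2 genomes; equal weights
  gs <- gs_from_pairs(
    a1 = c("hall", "conn", "spread"), a2 = c("hall", "conn"),
    b1 = c("hall", "conn"), b2 = c("hall", "spread"),
    c1 = c("rare", "spread"), c2 = c("other", "spread"),
    d1 = c("other", "spread"), d2 = c("other", "bg"))
  w <- equal_weights(gs)
  part <- stats::setNames(c(1, 1, 2, 2, 3, 3, 4, 4),
                          c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"))
  con <- identify_connectors(part, gs, w)
  sm <- list(S1 = c("a1", "a2", "b1", "b2"), S2 = c("c1", "c2", "d1", "d2"))
  hm <- classify_hallmark(con, sm, gs, w)
  # hall: connector (prev 1 in modules 1 and 2), prevalence 1 in S1
  expect_true(hm$hallmark[hm$family_id == "hall"])
  # conn: connector with S1 prevalence 0.75 > 0.35
  expect_true(hm$hallmark[hm$family_id == "conn"])
  # spread: connector across supermodules, prevalence 0.5 in both -> hallmark
  expect_true(hm$hallmark[hm$family_id == "spread"])
  # rare: present in one genome only, never a connector
  expect_false(hm$hallmark[hm$family_id == "rare"])
  # hallmark set is a subset of the connector set
  expect_true(all(hm$connector[hm$hallmark]))
  # fewer than two supermodules: empty hallmark set with a warning
  expect_warning(hm0 <- classify_hallmark(con, sm[1], gs, w), "fewer")
  expect_false(any(hm0$hallmark))
})

test_that("hallmark prevalence threshold separates connectors at 0.35", {
  # supermodule S1 = 3 modules x 5 genomes; `low` qualifies in modules 1-2
  # (prevalence 0.4 each) but its S1 prevalence 4/15 = 0.267 < 0.35;
  # `high` at 0.6 in both gives 6/15 = 0.4 > 0.35
  pres <- list(low = c("a1", "a2", "b1", "b2"),
               high = c("a1", "a2", "a3", "b1", "b2", "b3"))
  ids <- c(paste0("a", 1:5), paste0("b", 1:5), paste0("c", 1:5),
           paste0("z", 1:5))
  mb <- do.call(rbind, c(
    lapply(names(pres), function(f)
      data.frame(genome_id = pres[[f]], family_id = f, copy_count = 1L)),
    list(data.frame(genome_id = ids, family_id = "bg", copy_count = 1L))))
  gs <- genome_set(mb)
  w <- equal_weights(gs)
  part <- stats::setNames(rep(1:4, each = 5), ids)
  con <- identify_connectors(part, gs, w)
  sm <- list(S1 = ids[1:15], S2 = ids[16:20])
  hm <- classify_hallmark(con, sm, gs, w)
  expect_true(con$table$connector[con$table$family_id == "low"])
  expect_equal(hm$max_major_prevalence[hm$family_id == "low"], 4 / 15)
  expect_false(hm$hallmark[hm$family_id == "low"])
  expect_equal(hm$max_major_prevalence[hm$family_id == "high"], 0.4)
  expect_true(hm$hallmark[hm$family_id == "high"])
})

test_that("gene class precedence is hallmark > connector > signature", {
  con <- structure(list(table = data.frame(
    family_id = c("h", "c", "s", "o"), n_qualifying = c(3L, 2L, 1L, 0L),
    connector = c(TRUE, TRUE, FALSE, FALSE),
    modules = c("1,2,3", "1,2", "1", "")),
    prevalence = matrix(0, 0, 0), threshold = exp(-1)),
    class = "connector_table")
  hall <- data.frame(family_id = c("h", "c", "s", "o"),
                     max_major_prevalence = c(0.9, 0.2, 0.8, 0.1),
                     hallmark = c(TRUE, FALSE, FALSE, FALSE))
  sig <- data.frame(family_id = c("h", "c", "s", "o"),
                    mi_best = c(0.1, 0.2, 0.9, 0.3),
                    mi_second = c(0, 0, 0, 0),
                    best_module = "1",
                    signature = c(FALSE, FALSE, TRUE, FALSE))
  gc <- gene_classes(con, hall, sig)
  expect_equal(gc$class[match(c("h", "c", "s", "o"), gc$family_id)],
               c("hallmark", "connector", "signature", "other"))
})

test_that("betweenness matches a brute-force path-enumeration oracle", {
  # double star: hub family f0 on all shortest paths between private families
  mk <- list(g1 = c("f0", "p1"), g2 = c("f0", "p2"), g3 = c("f0", "p3"),
             g4 = c("f0", "p4"))
  gs <- do.call(gs_from_pairs, mk)
  net <- build_bipartite_network(gs)
  classes <- data.frame(family_id = c("f0", paste0("p", 1:4)),
                        class = c("hallmark", rep("other", 4)))
  acc <- betweenness_accounting(net, classes)
  oracle <- brute_betweenness(network_edges(net))
  expect_equal(acc$betweenness[names(oracle)], oracle, tolerance = 1e-9)
  expect_gt(acc$class_share["hallmark"], acc$class_share["other"])

  # complete bipartite graph: all gene nodes have equal betweenness
  gsc <- gs_from_pairs(g1 = paste0("f", 1:3), g2 = paste0("f", 1:3),
                       g3 = paste0("f", 1:3))
  netc <- build_bipartite_network(gsc)
  accc <- betweenness_accounting(netc, data.frame(family_id = paste0("f", 1:3),
                                                  class = "other"))
  expect_equal(length(unique(round(accc$betweenness[netc$family_ids], 9))), 1)

  # random small graphs against the oracle
  set.seed(61)
  for (i in 1:3) {
    netr <- random_bipartite(4, 5, p = 0.5)
    accr <- betweenness_accounting(netr, data.frame(family_id = netr$family_ids,
                                                    class = "other"))
    orr <- brute_betweenness(network_edges(netr))
    expect_equal(accr$betweenness[names(orr)], orr, tolerance = 1e-9)
  }
})
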