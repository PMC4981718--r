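# Small fixture builders used across the suite (everything generated in code).

# membership data.frame -> genome_set
gs_from_pairs <- function(...) {
  pairs <- list(...)
  mb <- do.call(rbind, lapply(names(pairs), function(g) {
    data.frame(genome_id = g, family_id = pairs[[g]], copy_count = 1L,
               stringsAsFactors = FALSE)
  }))
  genome_set(mb)
}

# two disjoint complete bipartite blocks K_{2,2}: known optimal Q = 0.5
two_block_network <- function() {
  mb <- data.frame(
    genome_id = rep(c("g1", "g2", "g3", "g4"), each = 2),
    family_id = c("f1", "f2", "f1", "f2", "f3", "f4", "f3", "f4"),
    copy_count = 1L, stringsAsFactors = FALSE)
  build_bipartite_network(genome_set(mb), giant_only = FALSE)
}

# random bipartite network with every node of degree >= 1
random_bipartite <- function(ng, nf, p = 0.5) {
  repeat {
    m <- matrix(stats::runif(ng * nf) < p, ng, nf)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  idx <- which(m, arr.ind = TRUE)
  mb <- data.frame(genome_id = paste0("g", idx[, 1]),
                   family_id = paste0("f", idx[, 2]),
                   copy_count = 1L, stringsAsFactors = FALSE)
  build_bipartite_network(genome_set(mb), giant_only = FALSE)
}

# equal-weight vector over a genome set
equal_weights <- function(gs) {
  ids <- gs$genomes$genome_id
  structure(stats::setNames(rep(1 / length(ids), length(ids)), ids),
            class = "weight_vector")
}

# star tree newick with given depths
star_newick <- function(depths) {
  paste0("(", paste(sprintf("t%d:%.6f", seq_along(depths), depths),
                    collapse = ","), ");")
}

# brute-force betweenness by BFS shortest-path enumeration (independent of
# igraph); returns named vector over the node ids of the edge list
brute_betweenness <- function(edges) {
  nodes <- unique(c(edges[[1]], edges[[2]]))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v])
  })
  bt <- stats::setNames(rep(0, length(nodes)), nodes)
  all_shortest <- function(s, t) {
    # BFS layers from s, then backtrack all shortest paths
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) && !is.finite(dist[t])) {
      nxt <- character(0)
      for (v in frontier) for (u in adj[[v]]) {
        if (!is.finite(dist[u])) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
      }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1]] <<- rev(acc); return() }
      for (u in adj[[v]]) if (dist[u] == dist[v] - 1) walk(u, c(acc, u))
    }
    walk(t, t)
    paths
  }
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    ps <- all_shortest(nodes[i], nodes[j])
    if (length(ps) == 0) next
    for (p in ps) {
      interior <- setdiff(p, c(nodes[i], nodes[j]))
      bt[interior] <- bt[interior] + 1 / length(ps)
    }
  }
  bt
}

nmi_to_truth <- function(partition, network, truth_modules) {
  truth <- truth_modules[network$genome_ids]
  got <- partition$labels[network$genome_ids]
  igraph::compare(as.integer(factor(truth)), as.integer(factor(got)),
                  method = "nmi")
}
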