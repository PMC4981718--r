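#' Barber bipartite modularity of a partition
#'
#' Exact evaluation of
#' `Q = (1/L) * sum_{i in G} sum_{j in F} (a_ij - k_i k_j / L) delta(m_i, m_j)`
#' where `a_ij` indicates a genome-family edge, `k` are node degrees, `L` the
#' edge count and `delta` compares module labels. The trivial partitions
#' (everything in one module; every node its own module) both score 0.
#'
#' @param network a `bipartite_network`.
#' @param partition a `partition` object or a named label vector covering
#'   every node of the network.
#' @return Q, a number in `[-1, 1]`.
#' @export
barber_modularity <- function(network, partition) {
  labels <- partition_labels(partition)
  nm <- igraph::V(network$graph)$name
  if (!all(nm %in% names(labels))) stop("partition must label every node")
  lab <- labels[nm]
  deg <- igraph::degree(network$graph)
  L <- igraph::ecount(network$graph)
  el <- network_edges(network)
  e_in <- sum(lab[el$genome_id] == lab[el$family_id])
  kg <- tapply(deg[network$genome_ids], lab[network$genome_ids], sum)
  kf <- tapply(deg[network$family_ids], lab[network$family_ids], sum)
  mods <- union(names(kg), names(kf))
  kg <- ifelse(is.na(kg[mods]), 0, kg[mods])
  kf <- ifelse(is.na(kf[mods]), 0, kf[mods])
  unname(e_in / L - sum(kg * kf) / L^2)
}

partition_labels <- function(partition) {
  if (inherits(partition, "partition")) partition$labels else partition
}

new_partition <- function(labels, network, Q = NULL) {
  labels <- stats::setNames(as.integer(factor(labels)), names(labels))
  p <- structure(list(labels = labels,
                      n_modules = length(unique(labels)),
                      Q = Q), class = "partition")
  if (is.null(Q)) p$Q <- barber_modularity(network, p)
  p
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", x$n_modules, "modules, Q =", format(x$Q, digits = 4), "\n")
  invisible(x)
}

#' Module membership of a partition as genome / family groups
#'
#' @param partition a `partition`.
#' @param network the `bipartite_network` it belongs to.
#' @return list with `genomes` and `families`: named lists mapping module
#'   label to member ids.
#' @export
partition_groups <- function(partition, network) {
  lab <- partition$labels
  g <- lab[network$genome_ids]
  f <- lab[network$family_ids]
  list(genomes = split(names(g), g), families = split(names(f), f))
}

#' Annealing schedule parameters
#'
#' @param t0 initial temperature; `NA` calibrates it from the typical
#'   magnitude of proposed moves so that roughly half of the uphill moves are
#'   accepted at the start.
#' @param cooling geometric cooling factor per sweep, in (0, 1).
#' @param sweep_factor single-node moves per sweep, as a multiple of the node
#'   count.
#' @param patience stop after this many times the node count of moves without
#'   improvement of the best Q (once the temperature has dropped).
#' @param fresh_prob probability that a move proposes a fresh (empty) module
#'   instead of a neighbor's module.
#' @param max_sweeps hard cap on sweeps.
#' @return a list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = NA, cooling = 0.995, sweep_factor = 1,
                            patience = 50, fresh_prob = 0.05,
                            max_sweeps = 2000) {
  if (!is.na(cooling) && (cooling <= 0 || cooling >= 1)) {
    stop("cooling must lie strictly inside (0, 1): the temperature must decrease")
  }
  structure(list(t0 = t0, cooling = cooling, sweep_factor = sweep_factor,
                 patience = patience, fresh_prob = fresh_prob,
                 max_sweeps = max_sweeps), class = "anneal_schedule")
}

network_edge_index <- function(network) {
  el <- network_edges(network)
  list(eg = match(el$genome_id, network$genome_ids) - 1L,
       ef = match(el$family_id, network$family_ids) - 1L,
       ng = length(network$genome_ids),
       nf = length(network$family_ids))
}

#' Optimize Barber modularity by simulated annealing
#'
#' Starting from singleton modules, repeatedly proposes single-node
#' reassignments to a neighboring (or fresh) module plus occasional
#' module-merge moves, accepting by the Metropolis rule under a geometric
#' cooling schedule, and finishes with a greedy polish so the returned
#' partition is a local maximum under the move set. Deterministic given
#' `seed`.
#'
#' @param network a `bipartite_network`.
#' @param seed integer seed.
#' @param schedule an [anneal_schedule()].
#' @return a `partition` (labels named by node, modularity `Q`).
#' @export
anneal_partition <- function(network, seed = 1, schedule = anneal_schedule()) {
  if (!inherits(schedule, "anneal_schedule")) {
    stop("schedule must be an anneal_schedule()")
  }
  idx <- network_edge_index(network)
  res <- with_seed(seed, cpp_sa_partition(
    idx$eg, idx$ef, idx$ng, idx$nf,
    t0 = ifelse(is.na(schedule$t0), -1, schedule$t0),
    cooling = schedule$cooling,
    fresh_prob = schedule$fresh_prob,
    sweep_factor = schedule$sweep_factor,
    patience_factor = schedule$patience,
    max_sweeps = as.integer(schedule$max_sweeps)))
  labels <- stats::setNames(res$labels,
                            c(network$genome_ids, network$family_ids))
  p <- new_partition(labels, network, Q = NULL)
  # consistency guard: the annealer's incremental Q must match the exact sum
  if (abs(p$Q - res$q) > 1e-9) {
    stop("internal error: incremental and exact modularity disagree")
  }
  p
}

#' Replicate module detection and consensus ensemble
#'
#' Runs `n_replicates` independent annealing replicates (per-replicate seeds
#' derived from the master seed), keeps the highest-Q partition as optimal
#' (ties broken by lowest replicate index) and summarizes the ensemble:
#' co-assignment matrices per node class (fraction of replicates in which a
#' node pair shares a module), per-module robustness and module-module
#' cross-similarity (see [robustness_matrices()]).
#'
#' @param network a `bipartite_network`.
#' @param n_replicates number of annealing replicates (default 100).
#' @param seed master seed.
#' @param schedule an [anneal_schedule()].
#' @return a list of class `partition_ensemble`: `replicates` (list of
#'   partitions), `best_index`, `best`, `co_genome`, `co_family`
#'   (co-assignment matrices), `robustness` (per-module data.frame),
#'   `cross_similarity` (module x module matrix), `network`.
#' @export
detect_modules <- function(network, n_replicates = 100, seed = 1,
                           schedule = anneal_schedule()) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  seeds <- derive_seeds(seed, n_replicates)
  reps <- lapply(seeds, function(s) anneal_partition(network, s, schedule))
  qs <- vapply(reps, function(p) p$Q, 0)
  best_index <- which.max(qs)           # which.max takes the first maximum
  ens <- structure(list(replicates = reps, best_index = best_index,
                        best = reps[[best_index]],
                        co_genome = co_assignment(reps, network$genome_ids),
                        co_family = co_assignment(reps, network$family_ids),
                        network = network),
                   class = "partition_ensemble")
  rb <- robustness_matrices(ens)
  ens$robustness <- rb$robustness
  ens$cross_similarity <- rb$cross_similarity
  ens
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat("partition_ensemble:", length(x$replicates), "replicates; best Q =",
      format(x$best$Q, digits = 4), "with", x$best$n_modules, "modules\n")
  invisible(x)
}

co_assignment <- function(replicates, ids) {
  n <- length(ids)
  co <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in replicates) {
    lab <- p$labels[ids]
    co <- co + outer(lab, lab, "==")
  }
  co / length(replicates)
}

#' Robustness and cross-similarity of modules in an ensemble
#'
#' The robustness of a module is the mean, over all its within-module node
#' pairs, of the fraction of replicates in which the pair was co-assigned,
#' computed separately for genome pairs and gene pairs (a module with no pair
#' of a class has robustness 1 by convention). The cross-similarity of two
#' distinct modules is the mean co-assignment fraction over genome pairs with
#' one member in each module.
#'
#' @param ensemble a `partition_ensemble`.
#' @return list with `robustness` (data.frame: `module`,
#'   `robustness_genomes`, `robustness_genes`, `n_genomes`, `n_genes`) and
#'   `cross_similarity` (module x module matrix; diagonal = genome
#'   robustness).
#' @export
robustness_matrices <- function(ensemble) {
  if (length(ensemble$replicates) < 1) stop("empty ensemble")
  grp <- partition_groups(ensemble$best, ensemble$network)
  mods <- sort(unique(c(names(grp$genomes), names(grp$families))))
  mean_pairs <- function(co, ids_a, ids_b = NULL) {
    if (is.null(ids_b)) {                       # within-group pairs
      if (length(ids_a) < 2) return(1)
      m <- co[ids_a, ids_a, drop = FALSE]
      mean(m[upper.tri(m)])
    } else {
      if (length(ids_a) == 0 || length(ids_b) == 0) return(NA_real_)
      mean(co[ids_a, ids_b, drop = FALSE])
    }
  }
  rob <- data.frame(
    module = mods,
    robustness_genomes = vapply(mods, function(m)
      mean_pairs(ensemble$co_genome, grp$genomes[[m]] %||% character(0)), 0),
    robustness_genes = vapply(mods, function(m)
      mean_pairs(ensemble$co_family, grp$families[[m]] %||% character(0)), 0),
    n_genomes = vapply(mods, function(m) length(grp$genomes[[m]] %||% character(0)), 0L),
    n_genes = vapply(mods, function(m) length(grp$families[[m]] %||% character(0)), 0L),
    stringsAsFactors = FALSE
  )
  cs <- matrix(NA_real_, length(mods), length(mods), dimnames = list(mods, mods))
  for (i in seq_along(mods)) for (j in seq_along(mods)) {
    a <- grp$genomes[[mods[i]]] %||% character(0)
    b <- grp$genomes[[mods[j]]] %||% character(0)
    cs[i, j] <- if (i == j) mean_pairs(ensemble$co_genome, a)
                else mean_pairs(ensemble$co_genome, a, b)
  }
  list(robustness = rob, cross_similarity = cs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degree-preserving randomization of a bipartite network
#'
#' Applies double-edge swaps `(g1,f1),(g2,f2) -> (g1,f2),(g2,f1)`, rejecting
#' swaps that would duplicate an edge, so every node keeps its exact degree.
#'
#' @param network a `bipartite_network`.
#' @param n_swaps number of attempted swaps (default `10 * |E|`).
#' @param seed integer seed.
#' @return a randomized `bipartite_network` on the same node set.
#' @export
rewire_bipartite <- function(network, n_swaps = NULL, seed = 1) {
  idx <- network_edge_index(network)
  L <- length(idx$eg)
  if (L < 2 || idx$ng < 2 || idx$nf < 2) stop("network too small to swap")
  if (is.null(n_swaps)) n_swaps <- 10L * L
  res <- with_seed(seed, cpp_edge_swap(idx$eg, idx$ef, idx$ng, idx$nf,
                                       as.integer(n_swaps)))
  mb <- data.frame(genome_id = network$genome_ids[res$eg + 1L],
                   family_id = network$family_ids[res$ef + 1L],
                   copy_count = 1L, stringsAsFactors = FALSE)
  build_bipartite_network(genome_set(mb), giant_only = FALSE)
}

#' Significance of a modularity value against a degree-preserving null
#'
#' Generates `n_null` degree-preserving randomizations of the network
#' (double-edge swaps), optimizes each with a reduced replicate count, and
#' reports the add-one estimate
#' `p = (1 + #\{null Q >= observed Q\}) / (1 + n_null)`, so p = 0 is never
#' reported from finitely many replicates.
#'
#' @param network a `bipartite_network`.
#' @param observed_Q the best modularity found on the real network (finite).
#' @param n_null number of null networks (default 100).
#' @param seed master seed.
#' @param n_replicates_null annealing replicates per null network (default 5).
#' @param schedule an [anneal_schedule()] used for the null optimizations.
#' @return list with `p_value`, `null_Q` (vector), `observed_Q`.
#' @export
partition_significance <- function(network, observed_Q, n_null = 100, seed = 1,
                                   n_replicates_null = 5,
                                   schedule = anneal_schedule(patience = 20,
                                                              max_sweeps = 1000)) {
  if (!is.finite(observed_Q)) stop("observed_Q must be finite")
  seeds <- derive_seeds(seed, 2 * n_null)
  null_Q <- vapply(seq_len(n_null), function(i) {
    rn <- rewire_bipartite(network, seed = seeds[2 * i - 1])
    ens <- detect_modules(rn, n_replicates = n_replicates_null,
                          seed = seeds[2 * i], schedule = schedule)
    ens$best$Q
  }, 0)
  list(p_value = (1 + sum(null_Q >= observed_Q)) / (1 + n_null),
       null_Q = null_Q, observed_Q = observed_Q)
}

#' Exhaustive best-modularity search on small networks
#'
#' Enumerates every set partition of the node set (restricted growth strings)
#' and returns the maximum Barber modularity. Intended as an oracle for small
#' graphs (about 12 nodes at most).
#'
#' @param network a small `bipartite_network`.
#' @return list with `Q` (the global maximum) and `labels` (a maximizing
#'   partition, named by node).
#' @export
best_partition_exhaustive <- function(network) {
  nm <- c(network$genome_ids, network$family_ids)
  n <- length(nm)
  if (n > 14) stop("exhaustive search limited to 14 nodes")
  ng <- length(network$genome_ids)
  deg <- igraph::degree(network$graph)[nm]
  L <- igraph::ecount(network$graph)
  el <- network_edges(network)
  ei <- match(el$genome_id, nm)
  ej <- match(el$family_id, nm)
  kg <- deg[seq_len(ng)]
  kf <- deg[(ng + 1):n]
  q_of <- function(lab) {
    e_in <- sum(lab[ei] == lab[ej])
    sg <- rowsum(kg, lab[seq_len(ng)])
    sf <- rowsum(kf, lab[(ng + 1):n])
    common <- intersect(rownames(sg), rownames(sf))
    e_in / L - sum(sg[common, 1] * sf[common, 1]) / L^2
  }
  # iterate restricted growth strings: a[1] = 0, a[i] <= max(a[1..i-1]) + 1
  a <- integer(n)
  bestQ <- -Inf; best <- a
  repeat {
    q <- q_of(a)
    if (q > bestQ + 1e-12) { bestQ <- q; best <- a }
    i <- n
    while (i > 1 && a[i] > max(a[seq_len(i - 1)])) i <- i - 1
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1):n] <- 0L
  }
  list(Q = bestQ, labels = stats::setNames(best + 1L, nm))
}

#' Write partition and ensemble summaries as TSV
#'
#' @param ensemble a `partition_ensemble`.
#' @param dir output directory (created if needed).
#' @return files written, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- ensemble$network
  lab <- ensemble$best$labels
  files <- character(0)
  f <- file.path(dir, "partition.tsv")
  write_tsv(data.frame(
    node_id = names(lab),
    node_class = ifelse(names(lab) %in% net$genome_ids, "genome", "family"),
    module = unname(lab)), f)
  files <- c(files, f)
  f <- file.path(dir, "robustness.tsv")
  write_tsv(ensemble$robustness, f)
  files <- c(files, f)
  for (nmat in c("co_genome", "co_family", "cross_similarity")) {
    f <- file.path(dir, paste0(nmat, ".tsv"))
    m <- ensemble[[nmat]]
    utils::write.table(m, f, sep = "\t", quote = FALSE, col.names = NA)
    files <- c(files, f)
  }
  invisible(files)
}
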