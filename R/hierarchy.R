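#' Identify connector genes between modules
#'
#' Computes the weighted prevalence of every family in every module of the
#' partition (modules taken as genome groups, prevalences from
#' [family_prevalence()]). A family qualifying (prevalence strictly above
#' `threshold`) in two or more modules is a connector; families qualifying in
#' exactly one module are retained in the module network but are not
#' connectors.
#'
#' @param partition a `partition` over the network's nodes.
#' @param genomes a [genome_set()] covering the partition's genomes.
#' @param weights a [genome_weights()] vector.
#' @param threshold prevalence threshold, default `exp(-1)`.
#' @param groups optional named list of genome-id groups overriding the
#'   partition's genome modules (used at supermodule levels).
#' @return a list of class `connector_table`: `table` (data.frame
#'   `family_id`, `n_qualifying`, `connector`, `modules` comma-separated) and
#'   `prevalence` (family x module matrix), plus the `threshold`.
#' @export
identify_connectors <- function(partition, genomes, weights,
                                threshold = exp(-1), groups = NULL) {
  if (is.null(groups)) {
    lab <- partition_labels(partition)
    glab <- lab[names(lab) %in% genomes$genomes$genome_id]
    groups <- split(names(glab), glab)
  }
  prev <- prevalence_matrix(genomes, weights, groups)
  qual <- prev > threshold
  nq <- rowSums(qual)
  tab <- data.frame(
    family_id = rownames(prev),
    n_qualifying = as.integer(nq),
    connector = nq >= 2,
    modules = apply(qual, 1, function(z) paste(colnames(prev)[z], collapse = ",")),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, prevalence = prev, threshold = threshold),
            class = "connector_table")
}

#' @export
print.connector_table <- function(x, ...) {
  cat("connector_table:", nrow(x$table), "families,",
      sum(x$table$connector), "connectors (threshold",
      format(x$threshold, digits = 4), ")\n")
  invisible(x)
}

#' Build the module-level bipartite network
#'
#' Higher-order network whose two node classes are modules and the gene
#' families shared by them: an edge joins a module and a family whenever the
#' family's prevalence in the module exceeds the connector threshold.
#' Families qualifying in a single module appear as degree-1 nodes.
#'
#' @param connectors an [identify_connectors()] result.
#' @return a `bipartite_network` with module-class nodes named `M<label>`.
#' @export
build_module_network <- function(connectors) {
  qual <- connectors$prevalence > connectors$threshold
  idx <- which(qual, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no family qualifies in any module: no edges")
  mb <- data.frame(
    genome_id = paste0("M", colnames(connectors$prevalence)[idx[, 2]]),
    family_id = rownames(connectors$prevalence)[idx[, 1]],
    copy_count = 1L, stringsAsFactors = FALSE)
  build_bipartite_network(genome_set(mb), giant_only = FALSE)
}

#' Iterated supermodule detection
#'
#' Starting from the primary modules, repeatedly (i) computes family
#' prevalences over the current (super)modules (genome unions with their
#' original weights), (ii) builds the module-connector bipartite network,
#' (iii) optimizes its Barber modularity with a replicate ensemble and tests
#' its significance against the degree-preserving null, and (iv) merges
#' (super)modules whose module-nodes were co-assigned in at least
#' `merge_threshold` of the replicates (single linkage over qualifying
#' pairs). Iteration stops when no merge occurs, modularity is not
#' significant, or `max_iterations` is exceeded (partial tree, with a
#' warning). Pairs co-assigned in `[0.25, merge_threshold)` of replicates are
#' reported as near-merges.
#'
#' @param partition the primary `partition`.
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector.
#' @param n_replicates annealing replicates per iteration (default 100).
#' @param seed master seed.
#' @param threshold connector prevalence threshold (default `exp(-1)`).
#' @param merge_threshold co-assignment fraction required to merge
#'   (default 0.5).
#' @param p_threshold modularity significance level (default 0.01).
#' @param n_null null networks per significance test (default 100).
#' @param max_iterations iteration cap.
#' @param schedule an [anneal_schedule()].
#' @return an object of class `hierarchy_tree`: `nodes` (data.frame `id`,
#'   `parent`, `iteration`, `robustness`, `type`), `membership` (primary
#'   module -> top-level supermodule), `supermodules` (named list of genome
#'   ids per top-level supermodule), `near_merges` (data.frame),
#'   `stop_reason`, `n_iterations`.
#' @export
detect_supermodules <- function(partition, genomes, weights,
                                n_replicates = 100, seed = 1,
                                threshold = exp(-1), merge_threshold = 0.5,
                                p_threshold = 0.01, n_null = 100,
                                max_iterations = 10,
                                schedule = anneal_schedule()) {
  lab <- partition_labels(partition)
  glab <- lab[names(lab) %in% genomes$genomes$genome_id]
  primary <- split(names(glab), glab)
  names(primary) <- paste0("M", names(primary))

  nodes <- data.frame(id = names(primary), parent = NA_character_,
                      iteration = 0L, robustness = NA_real_,
                      type = "module", stringsAsFactors = FALSE)
  groups <- primary                      # current top-level (super)module -> genomes
  near <- data.frame(a = character(0), b = character(0),
                     iteration = integer(0), co_fraction = numeric(0),
                     stringsAsFactors = FALSE)
  stop_reason <- NA_character_
  it <- 0L
  seeds <- derive_seeds(seed, 2L * max_iterations)

  while (it < max_iterations) {
    it <- it + 1L
    if (length(groups) < 2) { stop_reason <- "single group left"; break }
    con <- identify_connectors(NULL, genomes, weights, threshold = threshold,
                               groups = groups)
    if (!any(con$prevalence > threshold)) {
      stop_reason <- "no qualifying families"; break
    }
    mn <- tryCatch(build_module_network(con), error = function(e) NULL)
    if (is.null(mn)) { stop_reason <- "no qualifying families"; break }
    ens <- detect_modules(mn, n_replicates = n_replicates,
                          seed = seeds[2 * it - 1], schedule = schedule)
    sig <- tryCatch(
      partition_significance(mn, ens$best$Q, n_null = n_null,
                             seed = seeds[2 * it]),
      error = function(e) list(p_value = NA_real_))
    if (!is.na(sig$p_value) && sig$p_value >= p_threshold) {
      stop_reason <- sprintf("nonsignificant modularity (p = %.3f)", sig$p_value)
      break
    }
    # strip the M prefix used for module-class node ids inside the module network
    co <- ens$co_genome
    rownames(co) <- colnames(co) <- sub("^M", "", rownames(co))
    present <- intersect(names(groups), rownames(co))
    # single-linkage over pairs co-assigned in >= merge_threshold of replicates
    adj <- matrix(FALSE, length(groups), length(groups),
                  dimnames = list(names(groups), names(groups)))
    for (a in present) for (b in present) {
      if (a < b && co[a, b] >= merge_threshold) adj[a, b] <- adj[b, a] <- TRUE
    }
    for (a in present) for (b in present) {
      if (a < b && co[a, b] >= 0.25 && co[a, b] < merge_threshold) {
        near <- rbind(near, data.frame(a = a, b = b, iteration = it,
                                       co_fraction = co[a, b],
                                       stringsAsFactors = FALSE))
      }
    }
    gcl <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    if (max(gcl) == length(groups)) { stop_reason <- "no merge"; break }
    new_groups <- list()
    for (cl in unique(gcl)) {
      members <- names(gcl)[gcl == cl]
      if (length(members) == 1) {
        new_groups[[members]] <- groups[[members]]
        next
      }
      new_id <- sprintf("S%d_%d", it, length(new_groups) + 1L)
      prs <- utils::combn(members, 2)
      rb <- mean(co[cbind(prs[1, ], prs[2, ])])
      nodes <- rbind(nodes, data.frame(id = new_id, parent = NA_character_,
                                       iteration = it, robustness = rb,
                                       type = "supermodule",
                                       stringsAsFactors = FALSE))
      nodes$parent[nodes$id %in% members] <- new_id
      new_groups[[new_id]] <- unique(unlist(groups[members], use.names = FALSE))
    }
    groups <- new_groups
    if (it == max_iterations) {
      stop_reason <- "max_iterations exceeded"
      warning("supermodule search stopped at max_iterations; partial tree returned")
    }
  }
  if (is.na(stop_reason)) stop_reason <- "no iterations run"

  roots <- nodes$id[is.na(nodes$parent)]
  top_of <- function(id) {
    while (!is.na(nodes$parent[nodes$id == id])) id <- nodes$parent[nodes$id == id]
    id
  }
  leaf_ids <- nodes$id[nodes$type == "module"]
  membership <- stats::setNames(vapply(leaf_ids, top_of, ""), leaf_ids)
  structure(list(nodes = nodes, membership = membership,
                 supermodules = groups, near_merges = near,
                 stop_reason = stop_reason, n_iterations = it),
            class = "hierarchy_tree")
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  n_merge <- sum(x$nodes$type == "supermodule")
  cat("hierarchy_tree:", sum(x$nodes$type == "module"), "primary modules,",
      n_merge, "merge node(s),", length(x$supermodules),
      "top-level group(s); stopped:", x$stop_reason, "\n")
  invisible(x)
}

#' Number of merge events in a hierarchy
#' @param hierarchy a `hierarchy_tree`.
#' @return integer count of internal (supermodule) nodes.
#' @export
n_merges <- function(hierarchy) sum(hierarchy$nodes$type == "supermodule")

#' Render a hierarchy tree as newick
#'
#' Branch lengths are iteration counts (a leaf merged at iteration `i`
#' carries length `i`); internal node labels carry the merge robustness.
#' Forests are rendered as one newick string per root.
#'
#' @param hierarchy a `hierarchy_tree`.
#' @return character vector of newick strings.
#' @export
hierarchy_newick <- function(hierarchy) {
  nodes <- hierarchy$nodes
  render <- function(id, parent_iter) {
    row <- nodes[nodes$id == id, ]
    kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
    len <- abs(parent_iter - row$iteration)
    if (length(kids) == 0) {
      sprintf("%s:%g", id, len)
    } else {
      sprintf("(%s)%s:%g",
              paste(vapply(kids, render, "", parent_iter = row$iteration),
                    collapse = ","),
              format(row$robustness, digits = 3), len)
    }
  }
  roots <- nodes$id[is.na(nodes$parent)]
  vapply(roots, function(r) {
    iter <- nodes$iteration[nodes$id == r]
    paste0(render(r, iter), ";")
  }, "")
}

#' Re-analyze a subnetwork of selected modules
#'
#' Extracts the subnetwork spanned by the genomes assigned to the chosen
#' modules plus every family connected (but not necessarily assigned) to
#' them, and reruns replicate module detection on it. Limiting the scope this
#' way can resolve structure hidden by the resolution limit of modularity
#' optimization on the full network.
#'
#' @param network the full `bipartite_network`.
#' @param module_ids module labels (of `partition`) to dissect.
#' @param partition the primary `partition`.
#' @param n_replicates,seed,schedule passed to [detect_modules()].
#' @return a `partition_ensemble` on the subnetwork.
#' @export
dissect_subnetwork <- function(network, module_ids, partition,
                               n_replicates = 100, seed = 1,
                               schedule = anneal_schedule()) {
  lab <- partition_labels(partition)
  glab <- lab[network$genome_ids]
  keep_g <- names(glab)[glab %in% module_ids]
  if (length(keep_g) == 0) stop("module ids not present in partition")
  g <- network$graph
  fam <- unique(igraph::V(g)$name[unlist(igraph::adjacent_vertices(g, keep_g))])
  sub <- igraph::induced_subgraph(g, c(keep_g, fam))
  subnet <- new_bipartite_network(sub)
  if (igraph::ecount(sub) == 0) stop("empty subnetwork")
  detect_modules(subnet, n_replicates = n_replicates, seed = seed,
                 schedule = schedule)
}
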