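#' Merge highly redundant genomes into pangenomes
#'
#' Genomes whose shared-family fraction exceeds `share_threshold` are merged
#' transitively (single linkage) into pangenomes whose family set is the union
#' of the members. The shared fraction between genomes i and j is
#' `|F_i intersect F_j| / min(|F_i|, |F_j|)`, with families counted as sets
#' (ORFans included), biasing the denominator toward the smaller genome. Each
#' pangenome keeps the lexicographically smallest member id as its id; member
#' ids are recorded in the `members` metadata column.
#'
#' @param genomes a [genome_set()].
#' @param share_threshold merge when the shared fraction strictly exceeds this
#'   value (default 0.9); must lie in (0, 1].
#' Merging is iterated to a fixed point: unions can create new pangenome
#' pairs above the threshold, which are merged in turn, so the operation is
#' idempotent.
#'
#' @return a [genome_set()] of pangenomes, with a `members` column
#'   (comma-separated original ids) in its genome metadata.
#' @export
merge_redundant_genomes <- function(genomes, share_threshold = 0.9) {
  stopifnot(is_genome_set(genomes))
  if (share_threshold <= 0 || share_threshold > 1) {
    stop("share_threshold must lie in (0, 1]")
  }
  out <- merge_once(genomes, share_threshold)
  while (n_genomes(out) > 1) {
    nxt <- merge_once(out, share_threshold)
    if (n_genomes(nxt) == n_genomes(out)) break
    # fold member lists through the extra round
    prev_members <- stats::setNames(out$genomes$members, out$genomes$genome_id)
    nxt$genomes$members <- vapply(strsplit(nxt$genomes$members, ","),
                                  function(m) paste(sort(unlist(
                                    strsplit(prev_members[m], ","))),
                                    collapse = ","), "")
    out <- nxt
  }
  out
}

merge_once <- function(genomes, share_threshold) {
  inc <- incidence_matrix(genomes)
  sizes <- rowSums(inc)
  shared <- tcrossprod(inc * 1)               # |F_i intersect F_j|
  mins <- outer(sizes, sizes, pmin)
  frac <- shared / mins
  adj <- frac > share_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  ids <- genomes$genomes$genome_id
  mb <- genomes$membership
  mb$pan <- comp[match(mb$genome_id, ids)]
  rep_id <- vapply(split(ids, comp), function(m) min(m), "")
  members <- vapply(split(ids, comp),
                    function(m) paste(sort(m), collapse = ","), "")
  new_mb <- unique(data.frame(genome_id = rep_id[as.character(mb$pan)],
                              family_id = mb$family_id,
                              stringsAsFactors = FALSE))
  new_mb$copy_count <- 1L
  gmeta <- data.frame(genome_id = unname(rep_id),
                      members = unname(members),
                      stringsAsFactors = FALSE)
  # carry over taxon/lifestyle of the representative member
  m <- match(gmeta$genome_id, ids)
  gmeta$taxon <- genomes$genomes$taxon[m]
  gmeta$lifestyle <- genomes$genomes$lifestyle[m]
  out <- genome_set(new_mb, genomes = gmeta, families = genomes$families)
  out$genomes$members <- members[match(out$genomes$genome_id, rep_id)]
  out
}

#' Build the bipartite genome-gene family network
#'
#' One node per genome and per family; an edge whenever a genome carries at
#' least one copy of the family. Connected components are labeled; when
#' `giant_only = TRUE` (the default, matching the analysis universe) only the
#' largest component by node count is retained and the dropped nodes are
#' recorded.
#'
#' @param genomes a [genome_set()].
#' @param giant_only keep only the giant component?
#' @return an object of class `bipartite_network`: a list with the igraph
#'   `graph` (vertex attributes `name` and `type`, `FALSE` for genomes,
#'   `TRUE` for families), `genome_ids`, `family_ids`, and `dropped`
#'   (node names outside the giant component).
#' @export
build_bipartite_network <- function(genomes, giant_only = TRUE) {
  stopifnot(is_genome_set(genomes))
  gid <- genomes$genomes$genome_id
  fid <- genomes$families$family_id
  if (length(intersect(gid, fid))) {
    stop("genome and family ids must not collide")
  }
  edges <- rbind(genomes$membership$genome_id, genomes$membership$family_id)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(gid) + length(fid),
                            name = c(gid, fid),
                            type = c(rep(FALSE, length(gid)),
                                     rep(TRUE, length(fid))))
  g <- igraph::add_edges(g, match(as.vector(edges), c(gid, fid)))
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  dropped <- character(0)
  if (giant_only && comp$no > 1) {
    giant <- which.max(comp$csize)
    dropped <- igraph::V(g)$name[comp$membership != giant]
    g <- igraph::induced_subgraph(g, comp$membership == giant)
  }
  new_bipartite_network(g, dropped = dropped)
}

new_bipartite_network <- function(g, dropped = character(0)) {
  structure(list(graph = g,
                 genome_ids = igraph::V(g)$name[!igraph::V(g)$type],
                 family_ids = igraph::V(g)$name[igraph::V(g)$type],
                 dropped = dropped),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite_network:", length(x$genome_ids), "genomes,",
      length(x$family_ids), "families,", igraph::ecount(x$graph), "edges\n")
  if (length(x$dropped)) {
    cat("  dropped outside giant component:", length(x$dropped), "nodes\n")
  }
  invisible(x)
}

#' Edge list of a bipartite network
#' @param network a `bipartite_network`.
#' @return data.frame with columns `genome_id`, `family_id`.
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network$graph)
  fam_first <- el[, 1] %in% network$family_ids
  data.frame(genome_id = ifelse(fam_first, el[, 2], el[, 1]),
             family_id = ifelse(fam_first, el[, 1], el[, 2]),
             stringsAsFactors = FALSE)
}

#' Restrict a network to a set of core families
#'
#' Family nodes outside `core_families` are removed; genome nodes left with
#' degree zero are removed as well, so the result contains the core families
#' and the genomes with at least one core gene.
#'
#' @param network a `bipartite_network`.
#' @param core_families character vector of family ids to keep (non-empty).
#' @return a `bipartite_network`.
#' @export
restrict_to_core <- function(network, core_families) {
  if (length(core_families) == 0) stop("core_families must be non-empty")
  keep_f <- intersect(network$family_ids, core_families)
  if (length(keep_f) == 0) stop("no core family occurs in the network")
  g <- igraph::induced_subgraph(
    network$graph,
    igraph::V(network$graph)$name %in% c(network$genome_ids, keep_f))
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, iso)
  new_bipartite_network(g, dropped = c(network$dropped, iso))
}

#' Degree statistics and power-law fit of the family degree distribution
#'
#' Collects per-class degree vectors and histograms and fits the family-degree
#' exponent gamma of `P(k) ~ k^-gamma` by discrete maximum likelihood (see
#' [fit_power_exponent()]).
#'
#' @param network a `bipartite_network`.
#' @param k_min smallest degree included in the power-law fit.
#' @return a list of class `degree_profile` with elements `genome_degrees`,
#'   `family_degrees` (named vectors), `genome_hist`, `family_hist`
#'   (data.frames `k`, `count`), `gamma` (fitted exponent or `NA` when the
#'   degree list is degenerate) and `k_min`.
#' @export
degree_statistics <- function(network, k_min = 1) {
  if (igraph::vcount(network$graph) == 0) stop("empty network")
  deg <- igraph::degree(network$graph)
  kd_g <- deg[network$genome_ids]
  kd_f <- deg[network$family_ids]
  hist_of <- function(k) {
    tb <- table(k)
    data.frame(k = as.integer(names(tb)), count = as.integer(tb))
  }
  gamma <- tryCatch(fit_power_exponent(kd_f, k_min = k_min),
                    error = function(e) NA_real_)
  structure(list(genome_degrees = kd_g, family_degrees = kd_f,
                 genome_hist = hist_of(kd_g), family_hist = hist_of(kd_f),
                 gamma = gamma, k_min = k_min),
            class = "degree_profile")
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Fits the exponent of a discrete power law (zeta distribution)
#' `P(k) = k^-gamma / zeta(gamma, k_min)` to the degrees `k >= k_min`.
#' The default method maximizes the exact zeta likelihood numerically, which
#' is unbiased down to `k_min = 1`; `method = "approx"` uses the closed-form
#' continuity-corrected estimator
#' `1 + n / sum(log(k / (k_min - 0.5)))`, adequate only for larger `k_min`.
#'
#' @param k integer degree sample.
#' @param k_min smallest degree included in the fit.
#' @param method `"ml"` (exact discrete ML, default) or `"approx"`.
#' @return the fitted exponent (a single number > 1).
#' @export
fit_power_exponent <- function(k, k_min = 1, method = c("ml", "approx")) {
  method <- match.arg(method)
  k <- k[k >= k_min]
  if (length(k) < 2) stop("need at least two degrees >= k_min")
  if (length(unique(k)) == 1) stop("degenerate degree list: exponent undefined")
  if (method == "approx") {
    return(1 + length(k) / sum(log(k / (k_min - 0.5))))
  }
  # exact zeta likelihood: log L = -gamma * sum(log k) - n * log zeta(gamma, k_min)
  slk <- sum(log(k))
  n <- length(k)
  log_zeta <- function(gamma) {
    kk <- seq_len(20000L) + (k_min - 1L)
    s <- sum(kk^(-gamma))
    # integral tail bound beyond the partial sum
    tail <- (max(kk) + 0.5)^(1 - gamma) / (gamma - 1)
    log(s + tail)
  }
  nll <- function(gamma) gamma * slk + n * log_zeta(gamma)
  stats::optimize(nll, interval = c(1.0001, 12))$minimum
}

#' Bipartite clustering coefficients and their decay with degree
#'
#' Computes, for every node, the pairwise-overlap (Latapy) bipartite
#' clustering coefficient: the mean Jaccard overlap of its neighborhood with
#' the neighborhoods of its distance-2 neighbors (nodes of the same class
#' sharing at least one neighbor). Nodes with no distance-2 neighbor have an
#' undefined coefficient (`NA`) and are excluded from the `C(k)` curve. The
#' decay exponent alpha of `C(k) ~ k^-alpha` is fitted by least squares on
#' the log-log `C(k)` curve.
#'
#' @param network a `bipartite_network`.
#' @return a list of class `clustering_profile` with `coefficients` (named
#'   vector over all nodes), `curve` (data.frame `k`, `C`, per-degree means
#'   over both classes), `alpha` (fitted decay exponent, `NA` when the curve
#'   has fewer than 3 usable points).
#' @export
clustering_profile <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  adj <- igraph::as_adj_list(g)
  nm <- igraph::V(g)$name
  nbr <- lapply(adj, function(v) as.integer(v))
  cc <- rep(NA_real_, length(nbr))
  for (u in seq_along(nbr)) {
    nu <- nbr[[u]]
    if (length(nu) == 0) next
    second <- setdiff(unique(unlist(nbr[nu], use.names = FALSE)), u)
    if (length(second) == 0) next
    ov <- vapply(second, function(v) {
      nv <- nbr[[v]]
      length(intersect(nu, nv)) / length(union(nu, nv))
    }, 0)
    cc[u] <- mean(ov)
  }
  names(cc) <- nm
  deg <- igraph::degree(g)
  ok <- !is.na(cc)
  if (any(ok)) {
    curve <- aggregate(cc[ok], by = list(k = deg[ok]), FUN = mean)
    names(curve) <- c("k", "C")
  } else {
    curve <- data.frame(k = integer(0), C = numeric(0))
  }
  alpha <- NA_real_
  use <- curve$k > 0 & curve$C > 0
  if (sum(use) >= 3) {
    fit <- stats::lm(log(C) ~ log(k), data = curve[use, ])
    alpha <- -unname(stats::coef(fit)[2])
  }
  structure(list(coefficients = cc, curve = curve, alpha = alpha),
            class = "clustering_profile")
}

#' Summary statistics of a bipartite network
#'
#' The basic descriptors of a genome-gene family network: node counts, edge
#' count, edge density `|E| / (|genomes| * |families|)`, mean number of genes
#' per genome (mean genome degree) and mean gene abundance (mean family
#' degree, i.e. the mean number of genomes per family), optionally with
#' single-genome ORFan families excluded.
#'
#' @param network a `bipartite_network`.
#' @return data.frame with one row of summary fields.
#' @export
network_summary <- function(network) {
  deg <- igraph::degree(network$graph)
  kg <- deg[network$genome_ids]
  kf <- deg[network$family_ids]
  data.frame(
    genomes = length(kg),
    families = length(kf),
    edges = igraph::ecount(network$graph),
    edge_density = bipartite_edge_density(length(kg), length(kf),
                                          igraph::ecount(network$graph)),
    mean_genes_per_genome = mean(kg),
    mean_gene_abundance = mean(kf),
    mean_gene_abundance_no_orfans = if (any(kf > 1)) mean(kf[kf > 1]) else NA_real_
  )
}

#' Edge density of a bipartite graph from its counts
#'
#' @param n_genomes,n_families,n_edges node and edge counts.
#' @return `n_edges / (n_genomes * n_families)`.
#' @export
bipartite_edge_density <- function(n_genomes, n_families, n_edges) {
  if (n_genomes <= 0 || n_families <= 0) stop("node counts must be positive")
  n_edges / (n_genomes * n_families)
}

#' Write a bipartite network as GraphML and edge-list TSV
#'
#' @param network a `bipartite_network`.
#' @param graphml,edges optional output paths; write whichever is non-`NULL`.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml = NULL, edges = NULL) {
  out <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
    out <- c(out, graphml)
  }
  if (!is.null(edges)) {
    write_tsv(network_edges(network), edges)
    out <- c(out, edges)
  }
  invisible(out)
}
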