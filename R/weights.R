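#' Similarity-downweighted genome weights from a neighbor-joining tree
#'
#' Builds a neighbor-joining tree from the compositional distance matrix,
#' roots it at the midpoint, and assigns tree-proportional weights by the
#' Gerstein-Sonnhammer-Chothia (GSC) rule: each edge's length is divided
#' equally among the leaves below it and summed along every leaf's root path.
#' Clusters of closely related genomes thereby share weight instead of
#' dominating abundance sums. Negative NJ branch lengths are clamped to zero
#' (with a message); a tree of total length zero falls back to equal weights.
#'
#' @param distances a [distance_matrix()] (or plain symmetric matrix with
#'   dimnames) over at least one genome.
#' @return a named numeric vector of class `weight_vector` summing to 1, all
#'   entries > 0; its `"tree"` attribute carries the rooted NJ tree (`phylo`).
#' @export
genome_weights <- function(distances) {
  d <- unclass(distances)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have dimnames")
  n <- length(ids)
  if (any(!is.finite(d))) stop("distances must be finite")
  if (n == 1) {
    return(structure(stats::setNames(1, ids), class = "weight_vector"))
  }
  if (n == 2) {
    return(structure(stats::setNames(c(0.5, 0.5), ids), class = "weight_vector"))
  }
  phy <- ape::nj(stats::as.dist(d))
  if (any(phy$edge.length < 0)) {
    message("clamping ", sum(phy$edge.length < 0),
            " negative NJ branch length(s) to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phy <- phangorn::midpoint(phy)
  w <- gsc_weights(phy)
  structure(w[ids], class = "weight_vector", tree = phy)
}

#' Gerstein-Sonnhammer-Chothia leaf weights of a rooted tree
#'
#' Each edge's length is divided equally among the leaves of the clade below
#' the edge; a leaf's raw weight is the sum of its shares along the path to
#' the root. Weights are normalized to sum to 1. Leaves joined by zero-length
#' branches (e.g. identical genomes) share their clade's weight equally; a
#' tree with total length zero yields equal weights.
#'
#' @param phy a rooted `phylo` tree with branch lengths.
#' @return named numeric vector of normalized leaf weights.
#' @export
gsc_weights <- function(phy) {
  if (!inherits(phy, "phylo")) stop("need a phylo tree")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  ntip <- ape::Ntip(phy)
  if (ntip == 1) return(stats::setNames(1, phy$tip.label))
  # leaves below each node
  n_below <- rep(0L, ntip + phy$Nnode)
  n_below[seq_len(ntip)] <- 1L
  ord <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    n_below[ord$edge[e, 1]] <- n_below[ord$edge[e, 1]] + n_below[ord$edge[e, 2]]
  }
  # accumulate per-leaf shares root-down
  acc <- rep(0, ntip + phy$Nnode)
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; chl <- pre$edge[e, 2]
    acc[chl] <- acc[par] + pre$edge.length[e] / n_below[chl]
  }
  w <- acc[seq_len(ntip)]
  names(w) <- phy$tip.label
  if (sum(w) <= 0) w <- rep(1, ntip)                 # all-zero tree: equal weights
  w <- w / sum(w)
  if (any(w == 0)) {                                 # zero-length leaves share clade weight
    w <- w + 1e-12
    w <- w / sum(w)
  }
  w
}

#' Weighted abundance of a gene family
#'
#' The sum of the normalized weights of the genomes containing the family;
#' equal to 1 exactly when the family is present in every genome.
#'
#' @param family_id family id (must exist in `genomes`).
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector over the same genomes.
#' @return abundance in `[0, 1]`.
#' @export
family_abundance <- function(family_id, genomes, weights) {
  stopifnot(is_genome_set(genomes))
  if (!family_id %in% genomes$families$family_id) {
    stop("unknown family: ", family_id)
  }
  carriers <- genomes$membership$genome_id[genomes$membership$family_id == family_id]
  sum(weights[unique(carriers)])
}

#' Weighted prevalence of a gene family in a genome group
#'
#' The sum of weights of the group members carrying the family divided by the
#' total weight of the group. Over the whole genome set, prevalence equals
#' abundance.
#'
#' @param family_id family id.
#' @param group non-empty character vector of genome ids.
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector.
#' @return prevalence in `[0, 1]`.
#' @export
family_prevalence <- function(family_id, group, genomes, weights) {
  if (length(group) == 0) stop("empty group")
  carriers <- genomes$membership$genome_id[genomes$membership$family_id == family_id]
  sum(weights[intersect(group, carriers)]) / sum(weights[group])
}

#' Weighted prevalence of every family in every genome group
#'
#' Vectorized form of [family_prevalence()] over all families and a list of
#' genome groups (e.g. the modules of a partition).
#'
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector.
#' @param groups named list of genome-id vectors.
#' @return numeric matrix, families x groups.
#' @export
prevalence_matrix <- function(genomes, weights, groups) {
  inc <- incidence_matrix(genomes)            # genomes x families
  w <- as.numeric(weights[rownames(inc)])
  sapply(groups, function(g) {
    sel <- rownames(inc) %in% g
    colSums(inc[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
  })
}
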