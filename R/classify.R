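#' Normalized mutual information between a gene and a module
#'
#' Let `a, b, c, d` be the summed relative genome weights of (in-module and
#' carrying the gene), (outside and carrying), (in-module and lacking),
#' (outside and lacking), with `a + b + c + d = 1`. The statistic is
#' `MI = a log2(a / ((a+b)(a+c))) + d log2(d / ((c+d)(b+d)))`, i.e. the
#' mutual information with the `b` and `c` terms dropped so that genes with
#' patterns complementary to a module do not score, normalized by the joint
#' entropy `H = -sum_i i log2 i` over the four cells (`0 log 0 := 0`;
#' `H = 0` yields 0). It equals 1 exactly when the gene's weighted presence
#' pattern coincides with the module (`b = c = 0`) and 0 under exact
#' independence.
#'
#' @param family_id family id.
#' @param module character vector of genome ids forming the module.
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector (normalized over all genomes).
#' @return the normalized MI (can be negative for anti-associated patterns).
#' @export
normalized_mutual_information <- function(family_id, module, genomes, weights) {
  carriers <- unique(genomes$membership$genome_id[
    genomes$membership$family_id == family_id])
  ids <- genomes$genomes$genome_id
  w <- weights[ids]
  in_mod <- ids %in% module
  has <- ids %in% carriers
  w <- w / sum(w)
  nmi_cells(a = sum(w[in_mod & has]), b = sum(w[!in_mod & has]),
            cc = sum(w[in_mod & !has]), d = sum(w[!in_mod & !has]))
}

nmi_cells <- function(a, b, cc, d) {
  xlog2 <- function(x) ifelse(x > 0, log2(x), 0)
  mi <- 0
  if (a > 0) mi <- mi + a * (log2(a) - xlog2(a + b) - xlog2(a + cc))
  if (d > 0) mi <- mi + d * (log2(d) - xlog2(cc + d) - xlog2(b + d))
  h <- -sum(vapply(c(a, b, cc, d), function(x) x * xlog2(x), 0))
  if (h <= 0) return(0)
  mi / h
}

#' Normalized MI of every family against every module
#'
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector.
#' @param groups named list of genome-id groups (modules).
#' @return numeric matrix, families x modules.
#' @export
mi_matrix <- function(genomes, weights, groups) {
  inc <- incidence_matrix(genomes)
  w <- as.numeric(weights[rownames(inc)])
  w <- w / sum(w)
  out <- sapply(groups, function(g) {
    sel <- rownames(inc) %in% g
    a <- colSums(inc[sel, , drop = FALSE] * w[sel])
    b <- colSums(inc[!sel, , drop = FALSE] * w[!sel])
    cc <- sum(w[sel]) - a
    d <- sum(w[!sel]) - b
    vapply(seq_along(a), function(i) nmi_cells(a[i], b[i], cc[i], d[i]), 0)
  })
  rownames(out) <- colnames(inc)
  out
}

#' Classify hallmark genes
#'
#' A hallmark gene (i) is a connector between first-order modules and
#' (ii) has weighted prevalence above `prevalence_threshold` in at least one
#' of the two major supermodules (the two top-level supermodules containing
#' the most genomes). With fewer than two supermodules the hallmark set is
#' empty (with a warning).
#'
#' @param connectors an [identify_connectors()] result (primary modules).
#' @param hierarchy a `hierarchy_tree` from [detect_supermodules()], or a
#'   named list of genome-id vectors giving the supermodules directly.
#' @param genomes a [genome_set()].
#' @param weights a [genome_weights()] vector.
#' @param prevalence_threshold minimum supermodule prevalence (default 0.35).
#' @return data.frame: `family_id`, `connector`, `max_major_prevalence`,
#'   `hallmark`.
#' @export
classify_hallmark <- function(connectors, hierarchy, genomes, weights,
                              prevalence_threshold = 0.35) {
  tab <- connectors$table
  sm <- if (inherits(hierarchy, "hierarchy_tree")) hierarchy$supermodules
        else hierarchy
  out <- data.frame(family_id = tab$family_id, connector = tab$connector,
                    max_major_prevalence = NA_real_, hallmark = FALSE,
                    stringsAsFactors = FALSE)
  if (length(sm) < 2) {
    warning("fewer than 2 supermodules: hallmark set is empty")
    return(out)
  }
  sizes <- vapply(sm, length, 0L)
  major <- sm[order(-sizes)[1:2]]
  prev <- prevalence_matrix(genomes, weights, major)
  out$max_major_prevalence <- apply(prev[out$family_id, , drop = FALSE], 1, max)
  out$hallmark <- out$connector & out$max_major_prevalence > prevalence_threshold
  out
}

#' Classify signature genes from a normalized MI matrix
#'
#' A signature gene is diagnostic of a single module: its best-module
#' normalized MI exceeds `best_threshold` while the second best stays below
#' `second_threshold`. For single-module partitions the second-best MI is
#' defined as 0.
#'
#' @param mi a [mi_matrix()] (families x modules).
#' @param best_threshold default 0.6.
#' @param second_threshold default 0.02.
#' @return data.frame: `family_id`, `mi_best`, `mi_second`, `best_module`,
#'   `signature`.
#' @export
classify_signature <- function(mi, best_threshold = 0.6,
                               second_threshold = 0.02) {
  stopifnot(is.matrix(mi))
  ord <- t(apply(mi, 1, function(x) order(-x)[1:2]))
  mi_best <- mi[cbind(seq_len(nrow(mi)), ord[, 1])]
  mi_second <- if (ncol(mi) >= 2) mi[cbind(seq_len(nrow(mi)), ord[, 2])] else
    rep(0, nrow(mi))
  data.frame(
    family_id = rownames(mi),
    mi_best = mi_best,
    mi_second = mi_second,
    best_module = colnames(mi)[ord[, 1]],
    signature = mi_best > best_threshold & mi_second < second_threshold,
    stringsAsFactors = FALSE
  )
}

#' Full gene classification table
#'
#' Combines connector, hallmark and signature calls into one table with a
#' single `class` column using the precedence hallmark > connector >
#' signature > other (hallmark genes are connectors by definition; a
#' signature gene is never connector-qualified in two modules).
#'
#' @param connectors an [identify_connectors()] result.
#' @param hallmark a [classify_hallmark()] result.
#' @param signature a [classify_signature()] result.
#' @return data.frame of class `gene_class_table`.
#' @export
gene_classes <- function(connectors, hallmark, signature) {
  tab <- merge(merge(connectors$table, hallmark[, c("family_id",
                                                    "max_major_prevalence",
                                                    "hallmark")],
                     by = "family_id"),
               signature, by = "family_id")
  tab$class <- ifelse(tab$hallmark, "hallmark",
               ifelse(tab$connector, "connector",
               ifelse(tab$signature, "signature", "other")))
  class(tab) <- c("gene_class_table", "data.frame")
  tab
}

#' Betweenness accounting by gene class
#'
#' Computes exact unweighted shortest-path betweenness centrality (Brandes
#' convention: endpoints counted on paths but not toward their own
#' centrality) for every node of the bipartite network, then reports the
#' share of the total gene-node betweenness held by each gene class and the
#' class composition of the 50 highest-betweenness gene nodes. Disconnected
#' networks are computed per component and flagged.
#'
#' @param network a `bipartite_network`.
#' @param classes a [gene_classes()] table (or any data.frame with
#'   `family_id` and `class`).
#' @return list with `betweenness` (named vector over all nodes),
#'   `class_share` (named numeric; fraction of total gene betweenness per
#'   class), `top50` (data.frame of the top gene nodes), `connected` flag.
#' @export
betweenness_accounting <- function(network, classes) {
  g <- network$graph
  bt <- igraph::betweenness(g, directed = FALSE, weights = NA)
  fam_bt <- bt[network$family_ids]
  cls <- classes$class[match(network$family_ids, classes$family_id)]
  cls[is.na(cls)] <- "other"
  total <- sum(fam_bt)
  share <- if (total > 0) tapply(fam_bt, cls, sum) / total else
    tapply(fam_bt, cls, function(x) 0)
  ord <- order(-fam_bt)
  topn <- utils::head(ord, 50)
  top50 <- data.frame(family_id = network$family_ids[topn],
                      betweenness = fam_bt[topn],
                      class = cls[topn], stringsAsFactors = FALSE)
  list(betweenness = bt,
       class_share = stats::setNames(as.numeric(share), names(share)),
       top50 = top50,
       connected = igraph::is_connected(g))
}
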