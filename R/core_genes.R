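#' Compositional gene-content distance between two genomes
#'
#' Under a divergence model in which the shared-family fraction of two
#' genomes decays exponentially with time, the quantity
#' `D = -ln(S / sqrt(N_i * N_j))` is a natural distance, where `S` is the
#' number of shared families and `N_i`, `N_j` the repertoire sizes (the
#' geometric mean biases the denominator toward the smaller genome, guarding
#' against giant-genome artifacts). For disjoint repertoires (`S = 0`) a
#' conservative estimate `ln(1 + sqrt(N_i * N_j))` is used: the time for an
#' ancestor with one extra gene to lose all but that one shared gene.
#'
#' @param genome_i,genome_j character vectors of family ids (presence-based
#'   sets; duplicates ignored), both non-empty.
#' @return a non-negative distance.
#' @export
compositional_distance <- function(genome_i, genome_j) {
  genome_i <- unique(genome_i); genome_j <- unique(genome_j)
  ni <- length(genome_i); nj <- length(genome_j)
  if (ni == 0 || nj == 0) stop("empty genome")
  s <- length(intersect(genome_i, genome_j))
  if (s > 0) max(0, -log(s / sqrt(ni * nj))) else log(1 + sqrt(ni * nj))
}

#' All-pairs compositional distance matrix
#'
#' @param genomes a [genome_set()] (distances are computed on the
#'   presence-based family sets, typically after pangenome merging).
#' @return a symmetric matrix of class `c("distance_matrix", "matrix")` with
#'   zero diagonal, dimnames = genome ids.
#' @export
distance_matrix <- function(genomes) {
  stopifnot(is_genome_set(genomes))
  inc <- incidence_matrix(genomes)
  sizes <- rowSums(inc)
  if (any(sizes == 0)) stop("empty genome in set")
  shared <- tcrossprod(inc * 1)
  geo <- sqrt(outer(sizes, sizes))
  d <- -log(shared / geo)
  disjoint <- shared == 0
  d[disjoint] <- log(1 + geo[disjoint])
  d[d < 0] <- 0           # numeric guard: identical repertoires give exactly 0
  diag(d) <- 0
  class(d) <- c("distance_matrix", "matrix")
  d
}

#' Maximum likelihood loss rate from pattern distance vectors
#'
#' Core of the pure-loss estimator. Conditional on a family being present in
#' the common ancestor of a genome pair at divergence distance `D`, the
#' probability of seeing it in both genomes is `P11 = exp(-r D) / Z` and in
#' exactly one `P10 = 2 exp(-r D / 2) (1 - exp(-r D / 2)) / Z`, with
#' `Z = P10 + P11` (pairs lacking the family in both genomes carry no
#' information about ancestral presence and are excluded upstream). The MLE of
#' the relative loss rate `r` maximizes the summed log probability over the
#' observed patterns; it is found by 1-D bounded optimization and clamped to
#' `r_bounds` (boundary solutions are flagged).
#'
#' @param d11 distances of pairs where the family is present in both genomes.
#' @param d10 distances of pairs where it is present in exactly one genome.
#' @param r_bounds search interval for `r` (default `c(1e-6, 50)`).
#' @return a list with `r`, `log_lik`, `boundary` (`"lower"`, `"upper"` or
#'   `NA`) and the pattern counts `n11`, `n10`.
#' @export
loss_rate_mle <- function(d11, d10, r_bounds = c(1e-6, 50)) {
  d11 <- as.numeric(d11); d10 <- as.numeric(d10)
  if (length(d11) + length(d10) == 0) stop("no eligible pairs")
  if (any(c(d11, d10) < 0)) stop("distances must be >= 0")
  nll <- function(r) -sum(log_pattern_prob(r, d11, d10))
  # no observed loss: likelihood increases as r -> 0
  if (length(d10) == 0) {
    return(list(r = r_bounds[1], log_lik = -nll(r_bounds[1]),
                boundary = "lower", n11 = length(d11), n10 = 0L))
  }
  opt <- stats::optimize(nll, interval = r_bounds, tol = 1e-8)
  r <- opt$minimum
  boundary <- NA_character_
  # optimize never returns the exact endpoints; snap when the edge is better
  if (nll(r_bounds[1]) <= opt$objective) { r <- r_bounds[1]; boundary <- "lower" }
  if (nll(r_bounds[2]) < min(opt$objective, nll(r_bounds[1]))) {
    r <- r_bounds[2]; boundary <- "upper"
  }
  list(r = r, log_lik = -nll(r), boundary = boundary,
       n11 = length(d11), n10 = length(d10))
}

# summed log pattern probabilities at rate r (vectorized over pairs)
log_pattern_prob <- function(r, d11, d10) {
  lp <- function(d, both) {
    x <- exp(-r * d / 2)                    # per-genome survival over D/2
    z <- x^2 + 2 * x * (1 - x)              # P(present in >= 1) * Z-free form
    if (both) log(pmax(x^2, 1e-300)) - log(pmax(z, 1e-300))
    else log(pmax(2 * x * (1 - x), 1e-300)) - log(pmax(z, 1e-300))
  }
  c(if (length(d11)) lp(d11, TRUE), if (length(d10)) lp(d10, FALSE))
}

# For each family: distances of both-present and one-present eligible pairs.
family_pattern_distances <- function(pres, pair_i, pair_j, pair_d) {
  pi <- pres[pair_i]; pj <- pres[pair_j]
  both <- pi & pj
  one <- xor(pi, pj)
  list(d11 = pair_d[both], d10 = pair_d[one])
}

#' Estimate the loss rate of one gene family
#'
#' Applies [loss_rate_mle()] to the presence patterns of `family_id` over all
#' genome pairs closer than `max_distance` (distant pairs are excluded because
#' sporadically shared genes between unrelated genomes would bias the rate
#' downward). Pairs lacking the family in both genomes are discarded, as
#' ancestral presence is not guaranteed for them. Families appearing in fewer
#' than three genomes are not estimated.
#'
#' @param family_id a family id present in `genomes`.
#' @param genomes a [genome_set()].
#' @param distances a [distance_matrix()] over the same genomes.
#' @param max_distance pair eligibility threshold on `D` (default 1.0,
#'   strictly less-than).
#' @param r_bounds search interval for `r`.
#' @return as [loss_rate_mle()], or `r = NA` with `boundary = "not estimated"`
#'   when no eligible pair exists or the family appears fewer than 3 times.
#' @export
estimate_loss_rate <- function(family_id, genomes, distances,
                               max_distance = 1.0, r_bounds = c(1e-6, 50)) {
  stopifnot(is_genome_set(genomes))
  mb <- genomes$membership
  if (!family_id %in% genomes$families$family_id) {
    stop("unknown family: ", family_id)
  }
  ids <- genomes$genomes$genome_id
  d <- unclass(distances)[ids, ids]
  ut <- which(upper.tri(d) & d < max_distance, arr.ind = TRUE)
  pres <- ids %in% mb$genome_id[mb$family_id == family_id]
  if (sum(pres) < 3) {
    return(list(r = NA_real_, log_lik = NA_real_, boundary = "not estimated",
                n11 = NA_integer_, n10 = NA_integer_))
  }
  pat <- family_pattern_distances(pres, ut[, 1], ut[, 2],
                                  d[cbind(ut[, 1], ut[, 2])])
  if (length(pat$d11) + length(pat$d10) == 0) {
    return(list(r = NA_real_, log_lik = NA_real_, boundary = "not estimated",
                n11 = 0L, n10 = 0L))
  }
  loss_rate_mle(pat$d11, pat$d10, r_bounds = r_bounds)
}

#' Classify core genes by loss rate
#'
#' Estimates a loss rate for every family with at least three appearances
#' (over genome pairs with `D < max_distance`) and classifies as core the
#' families with `r < core_rate` (default 1, i.e. retention probability
#' `exp(-r)` above `exp(-1)`).
#'
#' @param genomes a [genome_set()] (typically pangenome-merged).
#' @param distances a [distance_matrix()] over the same genomes.
#' @param max_distance pair eligibility threshold (default 1.0).
#' @param core_rate loss-rate threshold for the core flag (default 1.0).
#' @param r_bounds search interval for `r`.
#' @return a data.frame of class `core_gene_table`: `family_id`,
#'   `appearances`, `n11`, `n10`, `r`, `retention` (= `exp(-r)`), `boundary`,
#'   `core` (logical).
#' @export
classify_core <- function(genomes, distances, max_distance = 1.0,
                          core_rate = 1.0, r_bounds = c(1e-6, 50)) {
  stopifnot(is_genome_set(genomes))
  ids <- genomes$genomes$genome_id
  d <- unclass(distances)
  if (!all(ids %in% rownames(d))) stop("distances do not cover all genomes")
  d <- d[ids, ids]
  ut <- which(upper.tri(d) & d < max_distance, arr.ind = TRUE)
  pair_d <- d[cbind(ut[, 1], ut[, 2])]
  inc <- incidence_matrix(genomes)
  fams <- genomes$families$family_id
  app <- colSums(inc)

  res <- lapply(seq_along(fams), function(fi) {
    if (app[fi] < 3) {
      return(list(r = NA_real_, boundary = "not estimated",
                  n11 = NA_integer_, n10 = NA_integer_))
    }
    pat <- family_pattern_distances(inc[, fi], ut[, 1], ut[, 2], pair_d)
    if (length(pat$d11) + length(pat$d10) == 0) {
      return(list(r = NA_real_, boundary = "not estimated", n11 = 0L, n10 = 0L))
    }
    fit <- loss_rate_mle(pat$d11, pat$d10, r_bounds = r_bounds)
    fit[c("r", "boundary", "n11", "n10")]
  })
  r <- vapply(res, function(x) x$r, 0)
  out <- data.frame(
    family_id = fams,
    appearances = as.integer(app),
    n11 = vapply(res, function(x) as.integer(x$n11), 0L),
    n10 = vapply(res, function(x) as.integer(x$n10), 0L),
    r = r,
    retention = exp(-r),
    boundary = vapply(res, function(x) as.character(x$boundary), ""),
    stringsAsFactors = FALSE
  )
  out$core <- !is.na(out$r) & out$r < core_rate & out$appearances >= 3
  class(out) <- c("core_gene_table", "data.frame")
  out
}

#' Write a core gene table as TSV, sorted by weighted abundance
#'
#' @param core_table a [classify_core()] result.
#' @param genomes the [genome_set()] it was computed from.
#' @param weights a [genome_weights()] vector (for the abundance column).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_core_table <- function(core_table, genomes, weights, path) {
  mb <- genomes$membership
  ab <- vapply(core_table$family_id, function(f) {
    carriers <- unique(mb$genome_id[mb$family_id == f])
    # genomes outside the weighted (core) set contribute nothing
    sum(weights[carriers], na.rm = TRUE)
  }, 0)
  out <- cbind(core_table, abundance = ab)
  out <- out[order(-out$abundance), ]
  write_tsv(out, path)
}
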