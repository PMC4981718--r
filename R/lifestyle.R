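#' Exact binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; the building block of the
#' module-lifestyle enrichment test.
#'
#' @param k observed count of the tested lifestyle.
#' @param n number of labeled genomes.
#' @param p0 background probability of that lifestyle.
#' @return the exact upper-tail probability in `(0, 1]`.
#' @export
lifestyle_binomial_p <- function(k, n, p0) {
  if (k < 0 || n < 1 || k > n) stop("need 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Lifestyle enrichment test for one module
#'
#' One-sided exact binomial test of whether the module's labeled members are
#' enriched for their majority lifestyle relative to the background
#' proportion, under the null that module composition is random with respect
#' to lifestyle. Modules in which fewer than `min_coverage` of the members
#' carry a label are flagged untested.
#'
#' @param members character vector of the module's genome ids.
#' @param genomes a [genome_set()] whose metadata holds `lifestyle` labels
#'   (`temperate` / `virulent` / `unknown`).
#' @param background optional named numeric
#'   `c(temperate = ..., virulent = ...)` background counts; defaults to the
#'   labeled-genome totals of `genomes`.
#' @param min_coverage minimum labeled fraction for testing (default 0.10).
#' @return a list: `tested`, `direction` (majority lifestyle), `k`, `n`,
#'   `p0`, `p_value` (NA when untested), `coverage`.
#' @export
module_lifestyle_test <- function(members, genomes, background = NULL,
                                  min_coverage = 0.10) {
  stopifnot(is_genome_set(genomes))
  meta <- genomes$genomes
  if (is.null(background)) {
    background <- c(temperate = sum(meta$lifestyle == "temperate"),
                    virulent = sum(meta$lifestyle == "virulent"))
  }
  if (sum(background) <= 0) stop("background counts must be positive")
  lab <- meta$lifestyle[match(members, meta$genome_id)]
  labeled <- lab[!is.na(lab) & lab != "unknown"]
  coverage <- length(labeled) / length(members)
  out <- list(tested = FALSE, direction = NA_character_, k = NA_integer_,
              n = length(labeled), p0 = NA_real_, p_value = NA_real_,
              coverage = coverage)
  if (length(labeled) == 0 || coverage < min_coverage) return(out)
  k_temp <- sum(labeled == "temperate")
  k_vir <- sum(labeled == "virulent")
  direction <- if (k_temp >= k_vir) "temperate" else "virulent"
  k <- max(k_temp, k_vir)
  p0 <- unname(background[direction] / sum(background))
  out$tested <- TRUE
  out$direction <- direction
  out$k <- as.integer(k)
  out$p0 <- p0
  out$p_value <- lifestyle_binomial_p(k, length(labeled), p0)
  out
}

#' Lifestyle tests over every module of a partition
#'
#' @param partition a `partition` (or named genome label vector).
#' @param genomes a [genome_set()] with lifestyle labels.
#' @param background,min_coverage see [module_lifestyle_test()].
#' @return data.frame with one row per module.
#' @export
lifestyle_tests <- function(partition, genomes, background = NULL,
                            min_coverage = 0.10) {
  lab <- partition_labels(partition)
  glab <- lab[names(lab) %in% genomes$genomes$genome_id]
  groups <- split(names(glab), glab)
  res <- lapply(groups, module_lifestyle_test, genomes = genomes,
                background = background, min_coverage = min_coverage)
  data.frame(
    module = names(groups),
    n_members = vapply(groups, length, 0L),
    coverage = vapply(res, function(x) x$coverage, 0),
    tested = vapply(res, function(x) x$tested, TRUE),
    direction = vapply(res, function(x) as.character(x$direction), ""),
    k = vapply(res, function(x) as.integer(x$k), 0L),
    n_labeled = vapply(res, function(x) as.integer(x$n), 0L),
    p0 = vapply(res, function(x) as.numeric(x$p0), 0),
    p_value = vapply(res, function(x) as.numeric(x$p_value), 0),
    stringsAsFactors = FALSE
  )
}
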