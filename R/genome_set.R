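#' Genome sets: the bipartite incidence data
#'
#' A `genome_set` holds the genome x gene-family membership data underlying a
#' bipartite gene-sharing network, together with optional genome metadata
#' (taxon, lifestyle). It is the common input container for all analysis
#' stages: genomes are one node class, gene families the other, and an edge is
#' drawn whenever a genome carries at least one copy of a family.
#'
#' @param membership data.frame with columns `genome_id`, `family_id`,
#'   `copy_count` (one row per genome/family pair; duplicate pairs are summed).
#' @param genomes optional data.frame of genome metadata with column
#'   `genome_id` and optionally `taxon` and `lifestyle` (one of `"temperate"`,
#'   `"virulent"`, `"unknown"`). Genomes absent from `membership` are dropped.
#' @param families optional data.frame of family metadata with column
#'   `family_id` and optionally `annotation`.
#'
#' @return An object of class `genome_set`: a list with elements `membership`
#'   (aggregated, character ids, integer counts), `genomes` and `families`
#'   (metadata tables).
#' @export
genome_set <- function(membership, genomes = NULL, families = NULL) {
  if (!is.data.frame(membership) || nrow(membership) == 0) {
    stop("`membership` must be a non-empty data.frame")
  }
  need <- c("genome_id", "family_id", "copy_count")
  miss <- setdiff(need, names(membership))
  if (length(miss)) stop("membership is missing column(s): ", paste(miss, collapse = ", "))
  membership$genome_id <- as.character(membership$genome_id)
  membership$family_id <- as.character(membership$family_id)
  cc <- membership$copy_count
  if (any(is.na(cc)) || any(cc != round(cc)) || any(cc < 1)) {
    stop("copy_count must be positive integers")
  }
  membership$copy_count <- as.integer(cc)
  # duplicate (genome, family) rows are summed into a single copy count
  key <- paste(membership$genome_id, membership$family_id, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(membership$copy_count, group = key, reorder = FALSE)
    ids <- strsplit(rownames(agg), "\r", fixed = TRUE)
    membership <- data.frame(
      genome_id = vapply(ids, `[`, "", 1L),
      family_id = vapply(ids, `[`, "", 2L),
      copy_count = as.integer(agg[, 1L]),
      stringsAsFactors = FALSE
    )
  }
  rownames(membership) <- NULL

  gid <- unique(membership$genome_id)
  fid <- unique(membership$family_id)
  gmeta <- data.frame(genome_id = gid, taxon = NA_character_,
                      lifestyle = "unknown", stringsAsFactors = FALSE)
  if (!is.null(genomes)) {
    genomes$genome_id <- as.character(genomes$genome_id)
    if (anyDuplicated(genomes$genome_id)) stop("duplicate genome_id in metadata")
    m <- match(gmeta$genome_id, genomes$genome_id)
    if ("taxon" %in% names(genomes)) gmeta$taxon <- as.character(genomes$taxon)[m]
    if ("lifestyle" %in% names(genomes)) {
      ls <- as.character(genomes$lifestyle)[m]
      ls[is.na(ls)] <- "unknown"
      bad <- setdiff(unique(ls), c("temperate", "virulent", "unknown"))
      if (length(bad)) stop("invalid lifestyle label(s): ", paste(bad, collapse = ", "))
      gmeta$lifestyle <- ls
    }
  }
  fmeta <- data.frame(family_id = fid, annotation = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(families)) {
    families$family_id <- as.character(families$family_id)
    m <- match(fmeta$family_id, families$family_id)
    if ("annotation" %in% names(families)) {
      fmeta$annotation <- as.character(families$annotation)[m]
    }
  }
  structure(list(membership = membership, genomes = gmeta, families = fmeta),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", nrow(x$genomes), "genomes,", nrow(x$families),
      "gene families,", nrow(x$membership), "memberships\n")
  nlab <- sum(x$genomes$lifestyle != "unknown")
  if (nlab > 0) cat("  lifestyle labels:", nlab, "\n")
  invisible(x)
}

#' @rdname genome_set
#' @param x object to test or print.
#' @export
is_genome_set <- function(x) inherits(x, "genome_set")

#' Number of genomes / families in a genome set
#' @param gs a [genome_set()].
#' @return integer count.
#' @export
n_genomes <- function(gs) nrow(gs$genomes)

#' @rdname n_genomes
#' @export
n_families <- function(gs) nrow(gs$families)

#' Family repertoires as a list of character vectors
#'
#' Presence-based family sets per genome (copy counts collapse to presence).
#'
#' @param gs a [genome_set()].
#' @return named list, one character vector of family ids per genome.
#' @export
family_sets <- function(gs) {
  sets <- split(gs$membership$family_id, gs$membership$genome_id)
  sets <- lapply(sets, unique)
  sets[gs$genomes$genome_id]
}

#' Presence/absence incidence matrix
#'
#' @param gs a [genome_set()].
#' @param sparse unused placeholder for interface stability; a dense logical
#'   matrix is returned (genomes x families).
#' @return logical matrix, rows = genomes, columns = families.
#' @export
incidence_matrix <- function(gs, sparse = FALSE) {
  gi <- match(gs$membership$genome_id, gs$genomes$genome_id)
  fi <- match(gs$membership$family_id, gs$families$family_id)
  m <- matrix(FALSE, n_genomes(gs), n_families(gs),
              dimnames = list(gs$genomes$genome_id, gs$families$family_id))
  m[cbind(gi, fi)] <- TRUE
  m
}

#' Subset a genome set
#'
#' Restrict to the given genomes and/or families; families (genomes) left with
#' no memberships are dropped, preserving the invariant that every family is
#' referenced by at least one genome.
#'
#' @param gs a [genome_set()].
#' @param genome_ids,family_ids character vectors of ids to keep (default all).
#' @return a [genome_set()].
#' @export
subset_genome_set <- function(gs, genome_ids = NULL, family_ids = NULL) {
  mb <- gs$membership
  if (!is.null(genome_ids)) mb <- mb[mb$genome_id %in% genome_ids, , drop = FALSE]
  if (!is.null(family_ids)) mb <- mb[mb$family_id %in% family_ids, , drop = FALSE]
  if (nrow(mb) == 0) stop("subset leaves no memberships")
  genome_set(mb, genomes = gs$genomes, families = gs$families)
}
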