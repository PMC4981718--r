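#' Read a genome-family membership table
#'
#' Reads a TSV with header columns `genome_id`, `family_id`, `copy_count`
#' (extra columns are ignored) and returns a validated [genome_set()].
#' Duplicate (genome, family) rows are summed into copy counts, so the
#' write/read round trip is the identity on aggregated tables.
#'
#' @param path path to the membership TSV.
#' @param metadata optional path to a genome metadata TSV with columns
#'   `genome_id` and optionally `taxon`, `lifestyle`.
#' @return a [genome_set()].
#' @export
read_genome_table <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("empty membership table: ", path)
  need <- c("genome_id", "family_id", "copy_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("membership table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  cc <- suppressWarnings(as.numeric(tab$copy_count))
  bad <- which(is.na(cc) | cc != round(cc) | cc < 1)
  if (length(bad)) {
    stop("non-integer or invalid copy_count at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tab$copy_count <- as.integer(cc)
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    if (!"genome_id" %in% names(meta)) {
      stop("metadata table ", metadata, " is missing column: genome_id")
    }
  }
  genome_set(tab[need], genomes = meta)
}

#' Write a genome set to TSV files
#'
#' @param gs a [genome_set()].
#' @param path output path for the membership TSV
#'   (`genome_id`, `family_id`, `copy_count`).
#' @param metadata optional output path for the genome metadata TSV
#'   (`genome_id`, `taxon`, `lifestyle`).
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(gs, path, metadata = NULL) {
  stopifnot(is_genome_set(gs))
  utils::write.table(gs$membership, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata)) {
    utils::write.table(gs$genomes, metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
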