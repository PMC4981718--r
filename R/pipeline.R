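#' Pipeline configuration
#'
#' Collects every threshold, replicate count and toggle of the end-to-end
#' analysis in one validated object. Defaults are the canonical analysis
#' settings: 90% pangenome merging, loss-rate core threshold 1, connector
#' threshold `exp(-1)`, hallmark prevalence 0.35, signature MI thresholds
#' 0.6 / 0.02, 50/100 merge vote, 10% lifestyle coverage, 100 module
#' replicates and 100 null networks.
#'
#' @param input path to a membership TSV, or a [genome_set()] directly.
#' @param metadata optional path to a genome metadata TSV.
#' @param out_dir output directory.
#' @param seed master seed; every stochastic stage draws its own sub-seed
#'   from it.
#' @param merge_threshold pangenome merge threshold (fraction, default 0.9).
#' @param core_rate loss-rate threshold for core genes (default 1.0).
#' @param max_distance pair-eligibility distance bound for loss rates.
#' @param connector_threshold prevalence threshold (default `exp(-1)`).
#' @param hallmark_threshold supermodule prevalence threshold (default 0.35).
#' @param signature_best,signature_second MI thresholds (0.6 / 0.02).
#' @param merge_vote co-assignment fraction required to merge supermodules.
#' @param lifestyle_coverage minimum labeled fraction per module (0.10).
#' @param n_replicates,n_null replicate counts (defaults 100 / 100).
#' @param n_replicates_null annealing replicates per null network.
#' @param use_core run module detection on the core subnetwork (default) or
#'   on the full network.
#' @param run_significance,run_hierarchy,run_classification,run_lifestyle
#'   stage toggles.
#' @param schedule an [anneal_schedule()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, metadata = NULL, out_dir = "vironet_out",
                            seed = 1,
                            merge_threshold = 0.9,
                            core_rate = 1.0,
                            max_distance = 1.0,
                            connector_threshold = exp(-1),
                            hallmark_threshold = 0.35,
                            signature_best = 0.6,
                            signature_second = 0.02,
                            merge_vote = 0.5,
                            lifestyle_coverage = 0.10,
                            n_replicates = 100,
                            n_null = 100,
                            n_replicates_null = 5,
                            use_core = TRUE,
                            run_significance = TRUE,
                            run_hierarchy = TRUE,
                            run_classification = TRUE,
                            run_lifestyle = TRUE,
                            schedule = anneal_schedule()) {
  if (missing(input)) stop("input is required")
  stopifnot(merge_threshold > 0, merge_threshold <= 1,
            core_rate > 0, max_distance > 0,
            connector_threshold > 0, connector_threshold < 1,
            hallmark_threshold > 0, hallmark_threshold < 1,
            signature_best > 0, signature_best < 1,
            signature_second >= 0, signature_second < 1,
            merge_vote > 0, merge_vote <= 1,
            lifestyle_coverage >= 0, lifestyle_coverage <= 1,
            n_replicates >= 1, n_null >= 1)
  if (!is.numeric(seed) || length(seed) != 1) stop("a seed is mandatory")
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

config_flat <- function(config) {
  keep <- !vapply(config, function(x) is.list(x) || is_genome_set(x), TRUE)
  # paths are run plumbing, not analysis parameters: keep them out of the
  # flattened config so reruns into different directories hash identically
  keep[names(config) %in% c("input", "metadata", "out_dir")] <- FALSE
  vals <- vapply(config[keep], function(x) paste(format(x), collapse = ","), "")
  c(paste0(names(config)[keep], "=", vals),
    paste0("schedule.", names(config$schedule), "=",
           vapply(config$schedule, format, "")))
}

#' Run the full analysis pipeline
#'
#' Executes merge, network construction, distances, loss rates, core
#' subnetwork, genome weighting, module detection, significance, supermodule
#' hierarchy, gene classification and lifestyle tests, writing every output
#' table under `config$out_dir` and returning the results with a manifest of
#' files written (stage-tagged, with the flattened config and its hash).
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result` with the per-stage objects
#'   (`genomes`, `pangenomes`, `network`, `distances`, `core_table`,
#'   `core_network`, `weights`, `ensemble`, `significance`, `hierarchy`,
#'   `connectors`, `classes`, `lifestyle`, `summary`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 8)
  manifest <- data.frame(stage = character(0), file = character(0),
                         stringsAsFactors = FALSE)
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = basename(file),
                                            stringsAsFactors = FALSE))
  }
  path <- function(f) file.path(config$out_dir, f)
  res <- list()

  gs <- if (is_genome_set(config$input)) config$input else
    read_genome_table(config$input, metadata = config$metadata)
  res$genomes <- gs
  message("input: ", n_genomes(gs), " genomes, ", n_families(gs), " families")

  res$pangenomes <- merge_redundant_genomes(gs, config$merge_threshold)
  write_genome_table(res$pangenomes, path("pangenomes.tsv"),
                     metadata = path("pangenome_metadata.tsv"))
  emit("merge", path("pangenomes.tsv")); emit("merge", path("pangenome_metadata.tsv"))
  message("merged into ", n_genomes(res$pangenomes), " pangenomes")

  res$network <- build_bipartite_network(res$pangenomes, giant_only = TRUE)
  write_network(res$network, edges = path("network_full.tsv"),
                graphml = path("network_full.graphml"))
  emit("network", path("network_full.tsv"))
  emit("network", path("network_full.graphml"))
  prof <- degree_statistics(res$network)
  deg <- c(prof$genome_degrees, prof$family_degrees)
  write_tsv(data.frame(
    node_id = names(deg),
    node_class = rep(c("genome", "family"), c(length(prof$genome_degrees),
                                              length(prof$family_degrees))),
    degree = unname(deg)), path("degrees.tsv"))
  emit("network", path("degrees.tsv"))
  res$degree_profile <- prof

  keep <- subset_genome_set(res$pangenomes, genome_ids = res$network$genome_ids,
                            family_ids = res$network$family_ids)
  res$distances <- distance_matrix(keep)

  analysis_net <- res$network
  analysis_gs <- keep
  if (config$use_core) {
    res$core_table <- classify_core(keep, res$distances,
                                    max_distance = config$max_distance,
                                    core_rate = config$core_rate)
    core_ids <- res$core_table$family_id[res$core_table$core]
    message(length(core_ids), " core families of ", nrow(res$core_table))
    res$core_network <- restrict_to_core(res$network, core_ids)
    analysis_net <- res$core_network
    analysis_gs <- subset_genome_set(keep,
                                     genome_ids = analysis_net$genome_ids,
                                     family_ids = analysis_net$family_ids)
  } else {
    message("core stage disabled: modules detected on the full network")
    emitted_dev <- data.frame(stage = "core", file = "(disabled)",
                              stringsAsFactors = FALSE)
    manifest <- rbind(manifest, emitted_dev)
  }
  res$weights <- genome_weights(res$distances[analysis_net$genome_ids,
                                              analysis_net$genome_ids])
  write_tsv(data.frame(genome_id = names(res$weights),
                       weight = as.numeric(res$weights)), path("weights.tsv"))
  emit("weights", path("weights.tsv"))
  tree <- attr(res$weights, "tree")
  if (!is.null(tree)) {
    ape::write.tree(tree, path("nj_tree.nwk"))
    emit("weights", path("nj_tree.nwk"))
  }
  if (config$use_core) {
    write_core_table(res$core_table, keep, res$weights,
                     path("core_genes.tsv"))
    emit("core", path("core_genes.tsv"))
  }

  res$ensemble <- detect_modules(analysis_net, config$n_replicates,
                                 seed = seeds[1], schedule = config$schedule)
  write_ensemble(res$ensemble, config$out_dir)
  for (f in c("partition.tsv", "robustness.tsv", "co_genome.tsv",
              "co_family.tsv", "cross_similarity.tsv")) emit("modules", path(f))
  message("best partition: ", res$ensemble$best$n_modules, " modules, Q = ",
          format(res$ensemble$best$Q, digits = 4))

  if (config$run_significance) {
    res$significance <- partition_significance(
      analysis_net, res$ensemble$best$Q, n_null = config$n_null,
      seed = seeds[2], n_replicates_null = config$n_replicates_null)
    message("partition significance: p = ",
            format(res$significance$p_value, digits = 3))
  }

  res$connectors <- identify_connectors(res$ensemble$best, analysis_gs,
                                        res$weights,
                                        threshold = config$connector_threshold)
  write_tsv(res$connectors$table, path("connectors.tsv"))
  emit("classify", path("connectors.tsv"))
  utils::write.table(res$connectors$prevalence, path("module_prevalence.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  emit("classify", path("module_prevalence.tsv"))

  if (config$run_hierarchy) {
    res$hierarchy <- detect_supermodules(
      res$ensemble$best, analysis_gs, res$weights,
      n_replicates = config$n_replicates, seed = seeds[3],
      threshold = config$connector_threshold,
      merge_threshold = config$merge_vote, n_null = config$n_null,
      schedule = config$schedule)
    writeLines(hierarchy_newick(res$hierarchy), path("hierarchy.nwk"))
    emit("hierarchy", path("hierarchy.nwk"))
    message("hierarchy: ", length(res$hierarchy$supermodules),
            " top-level supermodule(s) after ", res$hierarchy$n_iterations,
            " iteration(s)")
  }

  if (config$run_classification && config$run_hierarchy) {
    hm <- classify_hallmark(res$connectors, res$hierarchy, analysis_gs,
                            res$weights,
                            prevalence_threshold = config$hallmark_threshold)
    grp <- partition_groups(res$ensemble$best, analysis_net)$genomes
    mi <- mi_matrix(analysis_gs, res$weights, grp)
    sg <- classify_signature(mi, config$signature_best, config$signature_second)
    res$classes <- gene_classes(res$connectors, hm, sg)
    res$betweenness <- betweenness_accounting(analysis_net, res$classes)
    write_tsv(res$classes, path("gene_classes.tsv"))
    write_tsv(res$betweenness$top50, path("top_betweenness.tsv"))
    emit("classify", path("gene_classes.tsv"))
    emit("classify", path("top_betweenness.tsv"))
    cls_tab <- as.data.frame(table(class = res$classes$class),
                             stringsAsFactors = FALSE)
    names(cls_tab) <- c("class", "n_families")
    write_tsv(cls_tab, path("class_summary.tsv"))
    emit("classify", path("class_summary.tsv"))
    message("gene classes: ", sum(res$classes$class == "hallmark"),
            " hallmark, ", sum(res$classes$class == "connector"),
            " connector, ", sum(res$classes$class == "signature"),
            " signature")
  }

  if (config$run_lifestyle) {
    res$lifestyle <- lifestyle_tests(res$ensemble$best, analysis_gs,
                                     min_coverage = config$lifestyle_coverage)
    write_tsv(res$lifestyle, path("lifestyle_tests.tsv"))
    emit("lifestyle", path("lifestyle_tests.tsv"))
  }

  res$summary <- rbind(cbind(network = "full", network_summary(res$network)),
                       if (config$use_core)
                         cbind(network = "core", network_summary(res$core_network)))
  write_tsv(res$summary, path("summary.tsv"))
  emit("summary", path("summary.tsv"))

  flat <- config_flat(config)
  writeLines(flat, path("config.txt"))
  emit("config", path("config.txt"))
  manifest$config_hash <- config_hash(flat)
  write_tsv(manifest, path("manifest.tsv"))
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

# small stable polynomial hash of the flattened config (hex string)
config_hash <- function(lines) {
  bytes <- utf8ToInt(paste(lines, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:",
      paste(names(x)[!vapply(x, is.null, TRUE)], collapse = ", "), "\n")
  invisible(x)
}
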