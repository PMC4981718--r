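#' @useDynLib vironet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of reproducible sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Configuration for the planted-structure generator
#'
#' Encodes the generative conditions for a synthetic gene-sharing data set
#' with known modules, supermodules and gene archetypes: signature genes
#' confined to one module, connector genes shared by a pair of modules of the
#' same supermodule, hallmark genes spread across a whole supermodule, one-off
#' ORFans, and unstructured background noise families.
#'
#' Defaults describe a two-supermodule study system (2 supermodules of 4
#' modules of 15 genomes). Presence probabilities are chosen so that the
#' archetypes are separable by the analysis thresholds: signature and hallmark
#' genes at 0.9 (well above the connector threshold exp(-1) ~ 0.368), pairwise
#' connectors at 0.6, whose supermodule-wide prevalence 2 * 0.6 / 4 = 0.3
#' stays below the hallmark threshold 0.35.
#'
#' @param n_supermodules,modules_per_supermodule,genomes_per_module planted
#'   hierarchy shape (counts, all >= 1 for a non-empty output).
#' @param n_signature_per_module number of module-exclusive families per module.
#' @param p_signature presence probability of a signature family in each
#'   genome of its module.
#' @param n_connector_per_module_pair number of connector families for each
#'   unordered pair of modules within the same supermodule.
#' @param p_connector presence probability of a connector family in the
#'   genomes of its two linked modules.
#' @param n_hallmark_per_supermodule number of families spread across all
#'   modules of one supermodule.
#' @param p_hallmark presence probability of a hallmark family across its
#'   supermodule.
#' @param n_orfans_per_genome number of globally unique single-genome families
#'   attached to every genome.
#' @param n_noise_families,p_noise background families present in any genome
#'   independently with probability `p_noise`.
#' @param seed integer seed; the output is deterministic given the config.
#' @param strong_signal logical flag; when `TRUE`, requires
#'   `p_signature`, `p_connector` and `p_hallmark` to exceed exp(-1).
#' @return a list of class `planted_config`.
#' @export
planted_config <- function(n_supermodules = 2,
                           modules_per_supermodule = 4,
                           genomes_per_module = 15,
                           n_signature_per_module = 20,
                           p_signature = 0.9,
                           n_connector_per_module_pair = 2,
                           p_connector = 0.6,
                           n_hallmark_per_supermodule = 3,
                           p_hallmark = 0.9,
                           n_orfans_per_genome = 2,
                           n_noise_families = 40,
                           p_noise = 0.05,
                           seed = 1,
                           strong_signal = TRUE) {
  cfg <- list(n_supermodules = n_supermodules,
              modules_per_supermodule = modules_per_supermodule,
              genomes_per_module = genomes_per_module,
              n_signature_per_module = n_signature_per_module,
              p_signature = p_signature,
              n_connector_per_module_pair = n_connector_per_module_pair,
              p_connector = p_connector,
              n_hallmark_per_supermodule = n_hallmark_per_supermodule,
              p_hallmark = p_hallmark,
              n_orfans_per_genome = n_orfans_per_genome,
              n_noise_families = n_noise_families,
              p_noise = p_noise,
              seed = seed,
              strong_signal = strong_signal)
  counts <- cfg[grep("^n_|_per_", names(cfg))]
  counts <- cfg[c("n_supermodules", "modules_per_supermodule",
                  "genomes_per_module", "n_signature_per_module",
                  "n_connector_per_module_pair", "n_hallmark_per_supermodule",
                  "n_orfans_per_genome", "n_noise_families")]
  if (any(vapply(counts, function(x) x < 0 || x != round(x), TRUE))) {
    stop("all counts must be non-negative integers")
  }
  probs <- cfg[c("p_signature", "p_connector", "p_hallmark", "p_noise")]
  if (any(vapply(probs, function(p) p < 0 || p > 1, TRUE))) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (isTRUE(strong_signal)) {
    thr <- exp(-1)
    if (p_signature <= thr || p_connector <= thr || p_hallmark <= thr) {
      stop("strong-signal configs require p_signature, p_connector and ",
           "p_hallmark > exp(-1)")
    }
  }
  structure(cfg, class = "planted_config")
}

new_simulation_truth <- function(genome_module, genome_supermodule,
                                 family_class, family_module = NULL,
                                 true_loss_rate = NULL, tree = NULL) {
  structure(list(genome_module = genome_module,
                 genome_supermodule = genome_supermodule,
                 family_class = family_class,
                 family_module = family_module,
                 true_loss_rate = true_loss_rate,
                 tree = tree),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", length(x$genome_module), "genomes,",
      length(x$family_class), "families\n")
  print(table(x$family_class))
  invisible(x)
}

#' Generate a gene-sharing data set with planted modular structure
#'
#' Builds a synthetic genome x family membership table in which genomes fall
#' into known modules grouped into supermodules, and families follow the gene
#' archetypes encoded in the [planted_config()]: signature (module-exclusive),
#' connector (one module pair), hallmark (one whole supermodule), ORFan
#' (exactly one genome) and noise (unstructured background). Families that
#' happen to be realized in zero genomes are dropped from both the genome set
#' and the ground truth.
#'
#' @param config a [planted_config()].
#' @return a list with elements `genomes` (a [genome_set()]) and `truth`
#'   (a `simulation_truth` with genome module/supermodule labels and family
#'   class labels).
#' @export
generate_planted_network <- function(config) {
  if (!inherits(config, "planted_config")) config <- do.call(planted_config, config)
  n_mod <- config$n_supermodules * config$modules_per_supermodule
  n_gen <- n_mod * config$genomes_per_module
  if (n_gen == 0) stop("config yields zero genomes")

  genome_id <- sprintf("g%03d", seq_len(n_gen))
  gmod <- rep(seq_len(n_mod), each = config$genomes_per_module)
  gsup <- (gmod - 1L) %/% config$modules_per_supermodule + 1L

  rows_g <- list(); rows_f <- list()
  fam_class <- character(0); fam_module <- character(0); fam_id <- character(0)
  add_family <- function(id, class, module_lab, members) {
    fam_id <<- c(fam_id, id)
    fam_class <<- c(fam_class, class)
    fam_module <<- c(fam_module, module_lab)
    if (length(members)) {
      rows_g[[length(rows_g) + 1L]] <<- members
      rows_f[[length(rows_f) + 1L]] <<- rep(id, length(members))
    }
  }

  with_seed(config$seed, {
    for (m in seq_len(n_mod)) {
      idx <- which(gmod == m)
      for (s in seq_len(config$n_signature_per_module)) {
        keep <- idx[stats::runif(length(idx)) < config$p_signature]
        add_family(sprintf("sig_m%02d_%03d", m, s), "signature",
                   as.character(m), genome_id[keep])
      }
    }
    for (sm in seq_len(config$n_supermodules)) {
      mods <- which(((seq_len(n_mod) - 1L) %/% config$modules_per_supermodule + 1L) == sm)
      if (length(mods) >= 2) {
        prs <- utils::combn(mods, 2)
        for (p in seq_len(ncol(prs))) {
          idx <- which(gmod %in% prs[, p])
          for (s in seq_len(config$n_connector_per_module_pair)) {
            keep <- idx[stats::runif(length(idx)) < config$p_connector]
            add_family(sprintf("con_m%02d_m%02d_%02d", prs[1, p], prs[2, p], s),
                       "connector", paste(prs[, p], collapse = "+"),
                       genome_id[keep])
          }
        }
      }
      idx <- which(gsup == sm)
      for (s in seq_len(config$n_hallmark_per_supermodule)) {
        keep <- idx[stats::runif(length(idx)) < config$p_hallmark]
        add_family(sprintf("hal_s%d_%02d", sm, s), "hallmark",
                   paste0("S", sm), genome_id[keep])
      }
    }
    orf <- 0L
    for (g in seq_len(n_gen)) {
      for (s in seq_len(config$n_orfans_per_genome)) {
        orf <- orf + 1L
        add_family(sprintf("orf_%05d", orf), "orfan", NA_character_, genome_id[g])
      }
    }
    for (s in seq_len(config$n_noise_families)) {
      keep <- which(stats::runif(n_gen) < config$p_noise)
      add_family(sprintf("noi_%04d", s), "noise", NA_character_, genome_id[keep])
    }
  })

  mb <- data.frame(genome_id = unlist(rows_g), family_id = unlist(rows_f),
                   copy_count = 1L, stringsAsFactors = FALSE)
  if (nrow(mb) == 0) stop("config yields zero realized families")
  realized <- unique(mb$family_id)
  keep <- fam_id %in% realized
  truth <- new_simulation_truth(
    genome_module = stats::setNames(gmod, genome_id),
    genome_supermodule = stats::setNames(gsup, genome_id),
    family_class = stats::setNames(fam_class[keep], fam_id[keep]),
    family_module = stats::setNames(fam_module[keep], fam_id[keep])
  )
  gmeta <- data.frame(genome_id = genome_id, stringsAsFactors = FALSE)
  list(genomes = genome_set(mb, genomes = gmeta), truth = truth)
}

#' Simulate gene-content divergence by pure loss on a tree
#'
#' Every ancestral family is present at the root; along each branch of length
#' `t` a family with loss rate `r` survives with probability `exp(-r * t)`,
#' independently across families and branches. Leaves become genomes; their
#' repertoires are the families that survived the whole root-to-leaf path. No
#' gain occurs, matching the assumption of the loss-rate estimator
#' ([estimate_loss_rate()]). For leaves whose most recent common ancestor is
#' the root (e.g. any pair on a star tree), the expected fraction of ancestral
#' families retained in both genomes is `exp(-r * D)` with `D` the patristic
#' distance.
#'
#' @param tree a newick string (with branch lengths) or an [ape::phylo] tree.
#' @param n_ancestral_families number of families present at the root.
#' @param loss_rates positive per-family loss rates, length
#'   `n_ancestral_families` (recycled if length 1).
#' @param seed integer seed.
#' @return a list with `genomes` (a [genome_set()]; leaves that lose every
#'   family are dropped) and `truth` (a `simulation_truth` carrying the true
#'   loss rates, the tree as newick, and `"ancestral"` family class labels).
#' @export
simulate_pure_loss <- function(tree, n_ancestral_families, loss_rates, seed = 1) {
  if (is.character(tree)) {
    phy <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                    error = function(e) NULL)
    if (is.null(phy)) stop("malformed newick tree")
  } else if (inherits(tree, "phylo")) {
    phy <- tree
  } else stop("`tree` must be a newick string or a phylo object")
  if (is.null(phy) || ape::Ntip(phy) < 2) stop("tree must have >= 2 leaves")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("branch lengths must be >= 0")
  if (!length(loss_rates) %in% c(1L, n_ancestral_families)) {
    stop("loss_rates must have length 1 or n_ancestral_families")
  }
  loss_rates <- rep_len(as.numeric(loss_rates), n_ancestral_families)
  if (any(!is.finite(loss_rates)) || any(loss_rates <= 0)) {
    stop("loss rates must be positive")
  }

  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  fam_id <- sprintf("anc_%05d", seq_len(n_ancestral_families))

  # preorder traversal: presence propagates from root with per-branch survival
  pres <- matrix(FALSE, nnode, n_ancestral_families)
  pres[root, ] <- TRUE
  ord <- ape::reorder.phylo(phy, "cladewise")
  with_seed(seed, {
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; chl <- ord$edge[e, 2]
      t <- ord$edge.length[e]
      p_surv <- exp(-loss_rates * t)
      on <- pres[par, ]
      pres[chl, ] <- on & (stats::runif(n_ancestral_families) < p_surv)
    }
  })

  leaf_pres <- pres[seq_len(ntip), , drop = FALSE]
  rownames(leaf_pres) <- phy$tip.label
  idx <- which(leaf_pres, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("all families lost everywhere; nothing to return")
  mb <- data.frame(genome_id = phy$tip.label[idx[, 1]],
                   family_id = fam_id[idx[, 2]],
                   copy_count = 1L, stringsAsFactors = FALSE)
  gs <- genome_set(mb)
  truth <- new_simulation_truth(
    genome_module = stats::setNames(rep(1L, ntip), phy$tip.label),
    genome_supermodule = stats::setNames(rep(1L, ntip), phy$tip.label),
    family_class = stats::setNames(rep("ancestral", n_ancestral_families), fam_id),
    true_loss_rate = stats::setNames(loss_rates, fam_id),
    tree = ape::write.tree(phy)
  )
  list(genomes = gs, truth = truth)
}

#' Attach phage lifestyle labels to a simulated genome set
#'
#' Labels a fraction `coverage` of the genomes of each planted module as
#' temperate or virulent, drawing temperate with the module's probability from
#' `p_temperate_by_module`; unlabeled genomes keep the `"unknown"` label.
#'
#' @param genomes a [genome_set()].
#' @param truth the matching `simulation_truth` (for module labels).
#' @param p_temperate_by_module named numeric vector (names = module labels)
#'   of temperate probabilities; every module present in `truth` must appear.
#' @param coverage fraction of genomes per module that receive a label.
#' @param seed integer seed.
#' @return the genome set with its `lifestyle` metadata column filled in.
#' @export
attach_lifestyles <- function(genomes, truth, p_temperate_by_module,
                              coverage = 1, seed = 1) {
  stopifnot(is_genome_set(genomes))
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  if (any(p_temperate_by_module < 0 | p_temperate_by_module > 1)) {
    stop("temperate probabilities must lie in [0, 1]")
  }
  gmod <- truth$genome_module[genomes$genomes$genome_id]
  mods <- unique(as.character(gmod))
  miss <- setdiff(mods, names(p_temperate_by_module))
  if (length(miss)) stop("module(s) absent from p_temperate_by_module: ",
                         paste(miss, collapse = ", "))
  lifestyle <- rep("unknown", n_genomes(genomes))
  with_seed(seed, {
    for (m in mods) {
      idx <- which(as.character(gmod) == m)
      n_lab <- round(coverage * length(idx))
      if (n_lab == 0) next
      lab <- sample(idx, n_lab)
      temp <- stats::runif(n_lab) < p_temperate_by_module[[m]]
      lifestyle[lab] <- ifelse(temp, "temperate", "virulent")
    }
  })
  genomes$genomes$lifestyle <- lifestyle
  genomes
}

#' Write simulation ground truth as TSV tables
#'
#' @param truth a `simulation_truth`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "truth_genomes.tsv")
  write_tsv(data.frame(genome_id = names(truth$genome_module),
                       module = unname(truth$genome_module),
                       supermodule = unname(truth$genome_supermodule)), f)
  files <- c(files, f)
  f <- file.path(dir, "truth_families.tsv")
  fam <- data.frame(family_id = names(truth$family_class),
                    class = unname(truth$family_class))
  if (!is.null(truth$family_module)) fam$module <- unname(truth$family_module)
  if (!is.null(truth$true_loss_rate)) {
    fam$true_loss_rate <- unname(truth$true_loss_rate[fam$family_id])
  }
  write_tsv(fam, f)
  files <- c(files, f)
  if (!is.null(truth$tree)) {
    f <- file.path(dir, "truth_tree.nwk")
    writeLines(truth$tree, f)
    files <- c(files, f)
  }
  invisible(files)
}
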