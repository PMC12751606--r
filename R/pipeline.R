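#' Infer per-genome protein-protein interaction networks
#'
#' The end-to-end pipeline: featurize all proteomes, decide per-pair
#' similarity (threshold matching in `features` mode, the random-forest
#' classifier in `ml` mode), build phylogenetic profiles and conserved
#' gene-neighborhood evidence, sparsify oversized profile groups with the
#' stochastic interaction sampler, and assemble one undirected,
#' deduplicated, evidence-labeled network per genome. Results are a pure
#' function of (inputs, configuration, seed).
#'
#' @param genomes A directory of protein multi-FASTA files (one per genome,
#'   record order = gene order) or a list of
#'   [proteome][read_proteome_fasta] data.frames; at least 2 genomes.
#' @param mode `"features"` (default) or `"ml"`; `ml` requires `model`.
#' @param model A [pair_classifier][train_pair_classifier] (ml mode only).
#' @param propensity Propensity table used for featurization.
#' @param match_cfg [feature_match_config()] for Features-mode similarity
#'   (also the accept-first rule inside ml mode).
#' @param profile_cfg [profile_config()] for profile evidence and the
#'   sampling trigger.
#' @param neighborhood_cfg [neighborhood_config()] for neighborhood
#'   evidence.
#' @param seed Master seed; all stochastic stages derive their seeds from
#'   it.
#' @param include_isolated Include edge-less proteins in node sets?
#' @param similar Optional similarity predicate overriding both modes
#'   (e.g. the [truth_predicate()] of a simulation).
#' @return An object of class `ppi_run`: list with `networks` (one
#'   `ppi_network` per genome) and `manifest` (configuration echo, seed,
#'   versions, per-stage counts).
#' @examples
#' sim <- simulate_proteome_set(simulation_config(n_genomes = 3,
#'                                                genes_per_genome = 30,
#'                                                family_identity = 0.95,
#'                                                seed = 7))
#' run <- infer_ppi_networks(sim$genomes, similar = truth_predicate(sim))
#' summary(run)
#' @export
infer_ppi_networks <- function(genomes, mode = c("features", "ml"),
                               model = NULL,
                               propensity = default_propensity_table(),
                               match_cfg = feature_match_config(),
                               profile_cfg = profile_config(),
                               neighborhood_cfg = neighborhood_config(),
                               seed = 1L,
                               include_isolated = FALSE,
                               similar = NULL) {
  mode <- match.arg(mode)
  if (is.character(genomes) && length(genomes) == 1 && dir.exists(genomes)) {
    files <- sort(list.files(genomes, pattern = "\\.(fa|faa|fasta)$",
                             full.names = TRUE))
    if (length(files) < 2) {
      stop("need at least 2 FASTA files in ", genomes)
    }
    genomes <- lapply(files, read_proteome_fasta)
  }
  if (!is.list(genomes) || length(genomes) < 2) {
    stop("need at least 2 genomes")
  }
  genome_ids <- vapply(genomes, function(g) g$genome_id[1], "")
  if (anyDuplicated(genome_ids)) stop("duplicate genome ids")
  if (is.null(similar)) {
    similar <- if (mode == "ml") {
      if (is.null(model)) stop("ml mode requires a trained model")
      classifier_predicate(model, table = propensity, match_cfg = match_cfg)
    } else {
      features_predicate(table = propensity, cfg = match_cfg)
    }
  }
  n_g <- length(genomes)
  # similarity matrices, computed once and reused by both evidence stages
  sims <- vector("list", n_g)
  for (i in seq_len(n_g)) sims[[i]] <- vector("list", n_g)
  n_similar_pairs <- 0
  for (i in seq_len(n_g - 1)) {
    for (j in (i + 1):n_g) {
      sims[[i]][[j]] <- similar(genomes[[i]], genomes[[j]])
      n_similar_pairs <- n_similar_pairs + sum(sims[[i]][[j]])
    }
  }
  cached <- function(pi, pj) {
    i <- match(pi$genome_id[1], genome_ids)
    j <- match(pj$genome_id[1], genome_ids)
    if (i < j) sims[[i]][[j]] else t(sims[[j]][[i]])
  }
  profiles <- build_presence_profiles(genomes, cached)
  networks <- vector("list", n_g)
  counts <- data.frame(genome = genome_ids, proteins = NA_integer_,
                       profile_edges = NA_integer_,
                       neighborhood_edges = NA_integer_,
                       nodes = NA_integer_, edges = NA_integer_,
                       stringsAsFactors = FALSE)
  for (g in seq_len(n_g)) {
    pe <- profile_interactions(profiles, genome = g, cfg = profile_cfg,
                               seed = derive_seed(seed, 7L, g))
    ne <- neighborhood_interactions(genomes, cached, cfg = neighborhood_cfg,
                                    target = g)
    net <- assemble_network(list(pe, ne), genomes[[g]],
                            include_isolated = include_isolated)
    networks[[g]] <- net
    counts$proteins[g] <- nrow(genomes[[g]])
    counts$profile_edges[g] <- nrow(pe)
    counts$neighborhood_edges[g] <- nrow(ne)
    counts$nodes[g] <- length(net$nodes)
    counts$edges[g] <- nrow(net$edges)
  }
  names(networks) <- genome_ids
  manifest <- list(
    mode = if (is.null(model) && mode == "ml") "ml" else mode,
    seed = seed,
    genome_ids = genome_ids,
    n_similar_cross_genome_pairs = n_similar_pairs,
    match_cfg = unclass(match_cfg),
    profile_cfg = list(diff_tolerated = profile_cfg$diff_tolerated,
                       complete = profile_cfg$complete,
                       ris_trigger = profile_cfg$ris_trigger,
                       ris = unclass(profile_cfg$ris)),
    neighborhood_cfg = unclass(neighborhood_cfg),
    feature_layout = FEATURE_LAYOUT_VERSION,
    package_version = as.character(utils::packageVersion("gcppi")),
    counts = counts
  )
  structure(list(networks = networks, manifest = manifest),
            class = "ppi_run")
}

#' @export
print.ppi_run <- function(x, ...) {
  cat("<ppi_run> mode=", x$manifest$mode, ", seed=", x$manifest$seed,
      ", ", length(x$networks), " genome(s)\n", sep = "")
  for (nw in x$networks) {
    cat("  ", nw$genome_id, ": ", length(nw$nodes), " nodes, ",
        nrow(nw$edges), " edges\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ppi_run <- function(object, ...) {
  counts <- object$manifest$counts
  structure(list(counts = counts, mode = object$manifest$mode,
                 seed = object$manifest$seed),
            class = "summary.ppi_run")
}

#' @export
print.summary.ppi_run <- function(x, ...) {
  cat("Interaction networks (mode=", x$mode, ", seed=", x$seed, ")\n",
      sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write every network of a run as DOT files
#'
#' One DOT file per genome, named after the genome id.
#'
#' @param run A [ppi_run][infer_ppi_networks].
#' @param dir Output directory (created if missing). The run manifest is
#'   written alongside as `manifest.json`.
#' @return Invisibly, the output paths.
#' @export
write_run_dot <- function(run, dir) {
  stopifnot(inherits(run, "ppi_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(run$networks, function(nw) {
    write_network_dot(nw, file.path(dir, paste0(nw$genome_id, ".dot")))
  }, "")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
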