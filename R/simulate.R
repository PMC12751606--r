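# Synthetic multi-genome proteome simulator with full ground truth. The
# generator emulates the statistical structure the inference pipeline
# assumes: families of homologous proteins at controlled pairwise identity,
# conserved-vs-shuffled gene order, and presence/absence patterns across
# genomes that create phylogenetic-profile groups of controllable size.

#' Simulation configuration
#'
#' @param n_genomes Number of genomes (default 5).
#' @param genes_per_genome Number of gene families laid out along each
#'   genome (default 200); a genome carries the subset its presence pattern
#'   admits.
#' @param family_identity Expected pairwise identity between two orthologs
#'   of the same family, in \[0, 1\] (default 0.8). Substitutions are point
#'   replacements with a *different* residue; each ortholog diverges from
#'   the family ancestor at rate `1 - sqrt(family_identity)` so that
#'   ortholog pairs hit the target in expectation (up to the small
#'   back-coincidence term of two sites mutating to the same residue).
#' @param order_shuffle_rate Probability of swapping each adjacent gene pair
#'   during a local-shuffle pass (default 0: gene order fully conserved).
#' @param presence_pattern Optional list, one integer vector of genome
#'   indices per family, controlling presence/absence (default: every family
#'   in every genome). This is what shapes the phylogenetic-profile groups,
#'   including groups larger than the sampling trigger.
#' @param residue_composition Named 20-vector of residue frequencies
#'   (default: uniform over the standard amino acids); must sum to 1.
#' @param length_range Protein length range, sampled uniformly per family
#'   (default 120-360 residues).
#' @param seed Master seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 5L, genes_per_genome = 200L,
                              family_identity = 0.8,
                              order_shuffle_rate = 0,
                              presence_pattern = NULL,
                              residue_composition = NULL,
                              length_range = c(120L, 360L),
                              seed = 1L) {
  if (is.null(residue_composition)) {
    residue_composition <- setNames(rep(1 / 20, 20), AA20)
  }
  if (!setequal(names(residue_composition), AA20)) {
    stop("residue_composition must be named by the 20 standard amino acids")
  }
  if (abs(sum(residue_composition) - 1) > 1e-8) {
    stop("residue_composition must sum to 1")
  }
  if (family_identity < 0 || family_identity > 1) {
    stop("family_identity must be in [0, 1]")
  }
  if (order_shuffle_rate < 0 || order_shuffle_rate > 1) {
    stop("order_shuffle_rate must be in [0, 1]")
  }
  n_genomes <- as.integer(n_genomes)
  genes_per_genome <- as.integer(genes_per_genome)
  if (n_genomes < 2) stop("need at least 2 genomes")
  if (!is.null(presence_pattern)) {
    if (length(presence_pattern) != genes_per_genome) {
      stop("presence_pattern must have one entry per gene family")
    }
    ok <- vapply(presence_pattern, function(p)
      length(p) >= 1 && all(p %in% seq_len(n_genomes)), TRUE)
    if (!all(ok)) stop("presence_pattern entries must be non-empty subsets ",
                       "of the genome indices")
  }
  structure(list(n_genomes = n_genomes, genes_per_genome = genes_per_genome,
                 family_identity = family_identity,
                 order_shuffle_rate = order_shuffle_rate,
                 presence_pattern = presence_pattern,
                 residue_composition = residue_composition[AA20],
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

random_sequence <- function(len, composition) {
  paste(sample(AA20, len, replace = TRUE, prob = composition), collapse = "")
}

mutate_sequence <- function(sequence, p_sub, composition) {
  res <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(res)) < p_sub)
  for (i in hit) {
    others <- setdiff(AA20, res[i])
    res[i] <- sample(others, 1,
                     prob = composition[others] / sum(composition[others]))
  }
  paste(res, collapse = "")
}

sequence_identity <- function(a, b) {
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  if (length(ra) != length(rb)) stop("sequences of unequal length")
  mean(ra == rb)
}

#' Simulate a multi-genome proteome set with ground truth
#'
#' Draws one ancestral protein per family from the residue-composition
#' model, derives orthologs by seeded point substitution (targeting an
#' expected ortholog-pair identity of `family_identity`), lays genes out in
#' family order with
#' optional seeded local shuffles, and applies the presence/absence pattern.
#' The truth objects (family map, true profiles, true pairwise identities)
#' are returned alongside the proteomes, and the same seed reproduces the
#' output byte-identically.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional directory: when given, one FASTA file per genome and
#'   plain-text truth tables are written there.
#' @return A list of class `simulated_proteomes`: `genomes` (list of
#'   [proteome][read_proteome_fasta] data.frames), `truth` (list with
#'   `families` data.frame, `profiles` logical matrix family x genome,
#'   `identities` data.frame of within-family ortholog pair identities),
#'   and `config`.
#' @export
simulate_proteome_set <- function(cfg = simulation_config(), dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    nf <- cfg$genes_per_genome
    ng <- cfg$n_genomes
    pattern <- cfg$presence_pattern %||%
      rep(list(seq_len(ng)), nf)
    lens <- sample(cfg$length_range[1]:cfg$length_range[2], nf, replace = TRUE)
    ancestors <- vapply(lens, random_sequence,
                        "", composition = cfg$residue_composition)
    p_sub <- 1 - sqrt(cfg$family_identity)
    # member sequences per family per carrying genome
    members <- lapply(seq_len(nf), function(f) {
      gs <- pattern[[f]]
      seqs <- vapply(gs, function(g) {
        if (p_sub == 0) ancestors[f]
        else mutate_sequence(ancestors[f], p_sub, cfg$residue_composition)
      }, "")
      setNames(seqs, as.character(gs))
    })
    genomes <- vector("list", ng)
    fam_rows <- list()
    for (g in seq_len(ng)) {
      fams <- which(vapply(pattern, function(p) g %in% p, TRUE))
      ord <- fams
      if (cfg$order_shuffle_rate > 0 && length(ord) > 1) {
        for (i in seq_len(length(ord) - 1)) {
          if (runif(1) < cfg$order_shuffle_rate) {
            ord[c(i, i + 1)] <- ord[c(i + 1, i)]
          }
        }
      }
      ids <- sprintf("g%02d_f%04d", g, ord)
      genome_id <- sprintf("genome%02d", g)
      df <- data.frame(id = ids,
                       sequence = vapply(ord, function(f)
                         members[[f]][[as.character(g)]], ""),
                       genome_id = genome_id,
                       position = seq_along(ord) - 1L,
                       description = sprintf("family=%d seed=%d", ord,
                                             cfg$seed),
                       stringsAsFactors = FALSE)
      class(df) <- c("proteome", "data.frame")
      genomes[[g]] <- df
      fam_rows[[g]] <- data.frame(genome = genome_id, id = ids, family = ord,
                                  position = df$position,
                                  stringsAsFactors = FALSE)
    }
    profiles <- t(vapply(pattern, function(p) seq_len(ng) %in% p,
                         logical(ng)))
    colnames(profiles) <- sprintf("genome%02d", seq_len(ng))
    rownames(profiles) <- sprintf("f%04d", seq_len(nf))
    identities <- list()
    for (f in seq_len(nf)) {
      gs <- pattern[[f]]
      if (length(gs) < 2) next
      idx <- combn(length(gs), 2)
      identities[[length(identities) + 1]] <- data.frame(
        family = f,
        genome_a = sprintf("genome%02d", gs[idx[1, ]]),
        id_a = sprintf("g%02d_f%04d", gs[idx[1, ]], f),
        genome_b = sprintf("genome%02d", gs[idx[2, ]]),
        id_b = sprintf("g%02d_f%04d", gs[idx[2, ]], f),
        identity = apply(idx, 2, function(k)
          sequence_identity(members[[f]][[k[1]]], members[[f]][[k[2]]])),
        stringsAsFactors = FALSE)
    }
    truth <- list(families = do.call(rbind, fam_rows),
                  profiles = profiles,
                  identities = if (length(identities) > 0)
                    do.call(rbind, identities)
                  else data.frame())
    out <- structure(list(genomes = genomes, truth = truth, config = cfg),
                     class = "simulated_proteomes")
    if (!is.null(dir)) write_simulated_proteomes(out, dir)
    out
  })
}

write_simulated_proteomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) {
    path <- file.path(dir, paste0(g$genome_id[1], ".fasta"))
    writeLines(paste0(">", g$id, " ", g$description, "\n", g$sequence), path)
  }
  write.csv(sim$truth$families, file.path(dir, "truth_families.csv"),
            row.names = FALSE)
  write.csv(data.frame(family = rownames(sim$truth$profiles),
                       sim$truth$profiles),
            file.path(dir, "truth_profiles.csv"), row.names = FALSE)
  if (nrow(sim$truth$identities) > 0) {
    write.csv(sim$truth$identities, file.path(dir, "truth_identities.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Ground-truth similarity predicate of a simulation
#'
#' Returns the cross-genome predicate that declares two proteins similar iff
#' they belong to the same simulated family (optionally also requiring their
#' true pairwise identity to exceed a threshold). Useful as the oracle
#' against which feature- or classifier-based inference is checked.
#'
#' @param sim A [simulate_proteome_set()] result.
#' @param identity_threshold Optional minimum true pairwise identity.
#' @return A predicate `function(proteome_i, proteome_j)`.
#' @export
truth_predicate <- function(sim, identity_threshold = NULL) {
  stopifnot(inherits(sim, "simulated_proteomes"))
  fams <- sim$truth$families
  idmap <- setNames(fams$family, fams$id)
  ident <- sim$truth$identities
  ikeys <- if (nrow(ident) > 0) {
    setNames(ident$identity,
             paste(pmin(ident$id_a, ident$id_b),
                   pmax(ident$id_a, ident$id_b), sep = "\r"))
  } else numeric(0)
  function(pi, pj) {
    fi <- idmap[pi$id]; fj <- idmap[pj$id]
    m <- outer(fi, fj, "==")
    dimnames(m) <- list(pi$id, pj$id)
    if (!is.null(identity_threshold) && any(m)) {
      hits <- which(m, arr.ind = TRUE)
      keys <- paste(pmin(pi$id[hits[, 1]], pj$id[hits[, 2]]),
                    pmax(pi$id[hits[, 1]], pj$id[hits[, 2]]), sep = "\r")
      m[hits] <- ikeys[keys] > identity_threshold
    }
    m
  }
}

#' Simulate a labeled protein-pair dataset
#'
#' Positives are within-family ortholog pairs whose true pairwise identity
#' exceeds the labeling threshold; negatives are cross-family pairs drawn at
#' random. The negative count is controllable through `ratio`.
#'
#' @param cfg A [simulation_config()], or an existing
#'   [simulate_proteome_set()] result to reuse.
#' @param identity_threshold Labeling threshold on true pairwise identity
#'   (default 0.65: pairs above 65% identity are positive).
#' @param ratio Target negative:positive count ratio (default 3).
#' @param seed Seed for the negative-pair draw.
#' @return A data.frame of class `pair_dataset` with columns `id_a`, `id_b`,
#'   `seq_a`, `seq_b`, `identity` (NA for cross-family pairs) and `label`.
#' @export
simulate_pair_dataset <- function(cfg = simulation_config(),
                                  identity_threshold = 0.65,
                                  ratio = 3L, seed = 1L) {
  sim <- if (inherits(cfg, "simulated_proteomes")) cfg
         else simulate_proteome_set(cfg)
  ident <- sim$truth$identities
  if (nrow(ident) == 0) stop("simulation produced no within-family pairs")
  pos <- ident[ident$identity > identity_threshold, , drop = FALSE]
  if (nrow(pos) == 0) {
    stop("no family pair exceeds the identity threshold ", identity_threshold)
  }
  seqs <- do.call(rbind, sim$genomes)
  seqmap <- setNames(seqs$sequence, seqs$id)
  fammap <- setNames(sim$truth$families$family, sim$truth$families$id)
  n_neg <- as.integer(ratio) * nrow(pos)
  neg <- with_seed(seed, {
    ids <- names(fammap)
    out <- matrix(character(0), ncol = 2)
    guard <- 0L
    while (nrow(out) < n_neg && guard < 50L) {
      cand <- cbind(sample(ids, n_neg, replace = TRUE),
                    sample(ids, n_neg, replace = TRUE))
      keep <- fammap[cand[, 1]] != fammap[cand[, 2]]
      out <- unique(rbind(out, cand[keep, , drop = FALSE]))
      guard <- guard + 1L
    }
    out[seq_len(min(n_neg, nrow(out))), , drop = FALSE]
  })
  df <- rbind(
    data.frame(id_a = pos$id_a, id_b = pos$id_b,
               identity = pos$identity, label = TRUE,
               stringsAsFactors = FALSE),
    data.frame(id_a = neg[, 1], id_b = neg[, 2],
               identity = NA_real_, label = FALSE,
               stringsAsFactors = FALSE))
  df$seq_a <- unname(seqmap[df$id_a])
  df$seq_b <- unname(seqmap[df$id_b])
  class(df) <- c("pair_dataset", "data.frame")
  df
}
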