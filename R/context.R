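#' Phylogenetic-profile configuration
#'
#' @param diff_tolerated Tolerated Hamming distance between two profiles for
#'   them to be linked (default 0: identical profiles only).
#' @param complete If `TRUE` (default) profile predictions are emitted
#'   without additional filtering; if `FALSE`, identical-profile groups
#'   larger than `ris_trigger` are skipped entirely instead of sampled,
#'   reducing the prediction count.
#' @param ris_trigger Group size above which interaction sampling replaces
#'   the complete graph (default 100; the sampler fires for groups with
#'   *more than* this many members).
#' @param ris A [ris_config()] for the sampler.
#' @return An object of class `profile_config`.
#' @export
profile_config <- function(diff_tolerated = 0L, complete = TRUE,
                           ris_trigger = 100L, ris = ris_config()) {
  diff_tolerated <- as.integer(diff_tolerated)
  if (diff_tolerated < 0) stop("diff_tolerated must be >= 0")
  ris_trigger <- as.integer(ris_trigger)
  if (ris_trigger < 2) stop("ris_trigger must be >= 2")
  structure(list(diff_tolerated = diff_tolerated, complete = complete,
                 ris_trigger = ris_trigger, ris = ris),
            class = "profile_config")
}

#' Gene-neighborhood configuration
#'
#' @param w1 Main window size in genes (default 10).
#' @param cw1 Required number of distinct window genes with conserved
#'   counterparts (default 4); must not exceed `w1`.
#' @param expansion Window expansion mode: `"fixed"` (default) keeps the
#'   window at `w1`; `"dynamic"` starts at `dynamic_start` and grows by one
#'   while the conservation quota keeps being met, up to `w1`.
#' @param dynamic_start Starting window size in dynamic mode (default 3).
#' @return An object of class `neighborhood_config`.
#' @export
neighborhood_config <- function(w1 = 10L, cw1 = 4L,
                                expansion = c("fixed", "dynamic"),
                                dynamic_start = 3L) {
  expansion <- match.arg(expansion)
  w1 <- as.integer(w1); cw1 <- as.integer(cw1)
  if (w1 < 1 || cw1 < 1) stop("w1 and cw1 must be >= 1")
  if (cw1 > w1) stop("cw1 must not exceed w1")
  structure(list(w1 = w1, cw1 = cw1, expansion = expansion,
                 dynamic_start = as.integer(dynamic_start)),
            class = "neighborhood_config")
}

#' Build presence matrices and phylogenetic profiles
#'
#' For every protein of every genome, the profile bit for genome `g` is true
#' iff some protein of `g` is similar to it; the bit for the protein's own
#' genome is always true. Profile group size `x` counts proteins of the same
#' genome sharing an identical bit pattern.
#'
#' @param genomes A list of [proteome][read_proteome_fasta] data.frames
#'   (at least 2).
#' @param similar A symmetric cross-genome predicate:
#'   `function(proteome_i, proteome_j)` returning a logical matrix with one
#'   row per protein of the first argument and one column per protein of the
#'   second. See [features_predicate()] and [classifier_predicate()].
#' @return An object of class `presence_profiles`: list with `genome_ids`
#'   and, per genome, a logical `presence` matrix (proteins x genomes) and a
#'   `profiles` data.frame (`id`, `key`, `group_size`).
#' @export
build_presence_profiles <- function(genomes, similar) {
  if (length(genomes) < 2) {
    stop("phylogenetic profiles need at least 2 genomes")
  }
  genome_ids <- vapply(genomes, function(g) g$genome_id[1], "")
  n_g <- length(genomes)
  presence <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    mat <- matrix(FALSE, nrow(genomes[[i]]), n_g,
                  dimnames = list(genomes[[i]]$id, genome_ids))
    mat[, i] <- TRUE
    presence[[i]] <- mat
  }
  for (i in seq_len(n_g - 1)) {
    for (j in (i + 1):n_g) {
      s <- similar(genomes[[i]], genomes[[j]])
      stopifnot(nrow(s) == nrow(genomes[[i]]), ncol(s) == nrow(genomes[[j]]))
      presence[[i]][, j] <- rowSums(s) > 0
      presence[[j]][, i] <- colSums(s) > 0
    }
  }
  profiles <- lapply(presence, function(mat) {
    key <- apply(mat, 1, function(r) paste(as.integer(r), collapse = ""))
    size <- as.vector(table(key)[key])
    data.frame(id = rownames(mat), key = unname(key),
               group_size = unname(size), stringsAsFactors = FALSE)
  })
  structure(list(genome_ids = genome_ids, presence = presence,
                 profiles = profiles),
            class = "presence_profiles")
}

#' Diagnostic edge-count estimate for a conserved profile
#'
#' The accounting figure `f(x) = (x - 1)(x - 2) / 2` for a conserved
#' phylogenetic profile of `x` genes. Note this is a diagnostic, not the
#' generative rule: without sampling, a group of `x` identical profiles
#' contributes the complete graph of `x(x - 1)/2` edges, which `f(x)`
#' underestimates.
#'
#' @param x Integer group size, at least 2.
#' @return Integer edge estimate.
#' @examples
#' profile_edge_estimate(500) # 124251
#' @export
profile_edge_estimate <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 1 || is.na(x) || x < 2 || x != floor(x)) {
    stop("x must be a single integer >= 2")
  }
  (x - 1) * (x - 2) / 2
}

# Hamming distance between two 0/1 profile key strings.
profile_key_distance <- function(k1, k2) {
  sum(strsplit(k1, "")[[1]] != strsplit(k2, "")[[1]])
}

#' Profile-based interaction edges for one genome
#'
#' Links proteins of the target genome whose phylogenetic profiles differ in
#' at most `diff_tolerated` positions. Proteins whose profile is true only
#' at their own genome generate no edges. Identical-profile groups larger
#' than the sampling trigger are sparsified with [ris_sample()] instead of
#' completed.
#'
#' @param profiles A `presence_profiles` object, or the per-genome element
#'   of its `profiles` list.
#' @param genome Index or id of the target genome (when `profiles` is a
#'   `presence_profiles` object).
#' @param cfg A [profile_config()].
#' @param seed Seed for the interaction sampler.
#' @return A data.frame of canonical undirected edges (`a`, `b`) with an
#'   `evidence` column set to `"profile"`.
#' @export
profile_interactions <- function(profiles, genome = 1L,
                                 cfg = profile_config(), seed = 1L) {
  prof <- if (inherits(profiles, "presence_profiles")) {
    if (is.character(genome)) genome <- match(genome, profiles$genome_ids)
    profiles$profiles[[genome]]
  } else profiles
  stopifnot(is.data.frame(prof), all(c("id", "key") %in% names(prof)))
  # proteins present only in their own genome are uninformative
  informative <- vapply(prof$key,
                        function(k) sum(strsplit(k, "")[[1]] == "1") > 1,
                        TRUE)
  prof <- prof[informative, , drop = FALSE]
  if (nrow(prof) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  groups <- split(prof$id, prof$key)
  keys <- names(groups)
  edges <- list()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    x <- length(members)
    if (x < 2) next
    if (x > cfg$ris_trigger) {
      if (!cfg$complete) next
      e <- ris_sample(members, cfg$ris, seed = derive_seed(seed, 101L, gi))
    } else {
      e <- complete_graph_edges(members)
    }
    edges[[length(edges) + 1]] <- e
  }
  if (cfg$diff_tolerated > 0 && length(keys) > 1) {
    for (gi in seq_len(length(keys) - 1)) {
      for (gj in (gi + 1):length(keys)) {
        if (profile_key_distance(keys[gi], keys[gj]) <= cfg$diff_tolerated) {
          e <- expand.grid(a = groups[[gi]], b = groups[[gj]],
                           stringsAsFactors = FALSE)
          edges[[length(edges) + 1]] <- canonical_edges(e$a, e$b)
        }
      }
    }
  }
  out <- if (length(edges) > 0) {
    do.call(rbind, edges)
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }
  out <- canonical_edges(out$a, out$b)
  out$evidence <- rep("profile", nrow(out))
  out
}

# Window of `size` consecutive gene indices centered on `i`, truncated at
# sequence ends (no circular wraparound).
gene_window <- function(i, n, size) {
  left <- (size - 1L) %/% 2L
  right <- size - 1L - left
  max(1L, i - left):min(n, i + right)
}

#' Conserved gene-neighborhood interaction edges for one genome
#'
#' For each gene `g` of the target genome, a window of `w1` consecutive
#' genes centered on `g` is formed (truncated at contig ends, gene order =
#' record order). If another genome contains a gene similar to `g` whose own
#' window holds similar counterparts for at least `cw1` distinct genes of
#' `g`'s window, `g` is linked to each of those conserved window partners
#' (within the target genome). In dynamic mode the window starts at
#' `dynamic_start` genes and grows by one while the quota keeps being met,
#' up to `w1`.
#'
#' @param genomes List of [proteome][read_proteome_fasta] data.frames.
#' @param similar Cross-genome similarity predicate (as in
#'   [build_presence_profiles()]), or a pre-computed list `sim[[i]][[j]]` of
#'   logical matrices.
#' @param cfg A [neighborhood_config()].
#' @param target Index of the target genome.
#' @return A data.frame of canonical undirected edges with
#'   `evidence = "neighborhood"`.
#' @export
neighborhood_interactions <- function(genomes, similar,
                                      cfg = neighborhood_config(),
                                      target = 1L) {
  stopifnot(length(genomes) >= 2)
  n_g <- length(genomes)
  tg <- genomes[[target]]
  n <- nrow(tg)
  others <- setdiff(seq_len(n_g), target)
  # similarity matrices target x other, one per other genome
  sims <- lapply(others, function(j) {
    s <- if (is.function(similar)) similar(genomes[[target]], genomes[[j]])
         else if (target < j) similar[[target]][[j]]
         else t(similar[[j]][[target]])
    stopifnot(nrow(s) == n, ncol(s) == nrow(genomes[[j]]))
    s
  })
  a <- character(0); b <- character(0)
  sizes <- if (cfg$expansion == "fixed") cfg$w1
           else cfg$dynamic_start:cfg$w1
  for (i in seq_len(n)) {
    conserved <- integer(0)
    for (oi in seq_along(others)) {
      s <- sims[[oi]]
      m <- ncol(s)
      anchors <- which(s[i, ])
      if (length(anchors) == 0) next
      for (j in anchors) {
        best <- NULL
        for (size in sizes) {
          w_t <- gene_window(i, n, size)
          w_o <- gene_window(j, m, size)
          hit <- w_t[vapply(w_t, function(w) any(s[w, w_o]), TRUE)]
          if (length(hit) >= cfg$cw1) best <- hit else if (cfg$expansion == "dynamic") break
        }
        if (!is.null(best)) conserved <- union(conserved, setdiff(best, i))
      }
    }
    if (length(conserved) > 0) {
      a <- c(a, rep(tg$id[i], length(conserved)))
      b <- c(b, tg$id[conserved])
    }
  }
  out <- canonical_edges(a, b)
  out$evidence <- rep("neighborhood", nrow(out))
  out
}

new_ppi_network <- function(genome_id, edges, nodes) {
  structure(list(genome_id = genome_id,
                 nodes = sort(unique(as.character(nodes))),
                 edges = edges),
            class = "ppi_network")
}

#' Assemble a per-genome interaction network
#'
#' Merges evidence-labeled edge sets into one undirected, deduplicated
#' network. Evidence labels of coincident edges are unioned (comma-joined,
#' sorted). By default the node set contains only proteins that take part in
#' at least one edge; isolated proteins can be included explicitly.
#'
#' @param edge_sets List of edge data.frames (`a`, `b`, `evidence`).
#' @param genome A [proteome][read_proteome_fasta] data.frame, or a
#'   character vector of valid protein ids for the target genome.
#' @param genome_id Genome identifier (defaults to the proteome's).
#' @param include_isolated Include edge-less proteins in the node set?
#' @return A `ppi_network` object.
#' @export
assemble_network <- function(edge_sets, genome, genome_id = NULL,
                             include_isolated = FALSE) {
  ids <- if (is.data.frame(genome)) genome$id else as.character(genome)
  if (is.null(genome_id)) {
    genome_id <- if (is.data.frame(genome)) genome$genome_id[1] else "network"
  }
  all <- do.call(rbind, c(list(data.frame(a = character(0), b = character(0),
                                          evidence = character(0),
                                          stringsAsFactors = FALSE)),
                          edge_sets))
  foreign <- setdiff(unique(c(all$a, all$b)), ids)
  if (length(foreign) > 0) {
    stop("edge endpoint(s) not in target genome: ",
         paste(head(foreign, 5), collapse = ", "))
  }
  cano <- canonical_edges(all$a, all$b)
  if (nrow(all) > 0) {
    aa <- pmin(all$a, all$b); bb <- pmax(all$a, all$b)
    key <- paste(aa, bb, sep = "\r")
    ev <- tapply(all$evidence, key, function(e)
      paste(sort(unique(unlist(strsplit(e, ",")))), collapse = ","))
    cano$evidence <- unname(ev[edge_keys(cano)])
  } else {
    cano$evidence <- character(0)
  }
  nodes <- if (include_isolated) ids else unique(c(cano$a, cano$b))
  new_ppi_network(genome_id, cano, nodes)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> genome=", x$genome_id, ": ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param network A `ppi_network`.
#' @return An undirected `igraph` graph with an `evidence` edge attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  g
}

#' @export
plot.ppi_network <- function(x, ...) {
  igraph::plot.igraph(as_igraph(x), vertex.size = 4, vertex.label.cex = 0.6,
                      ...)
  invisible(x)
}

#' Features-mode similarity predicate
#'
#' Builds the cross-genome predicate used by [build_presence_profiles()] and
#' [neighborhood_interactions()]: proteomes are featurized once (cached) and
#' pairs are compared with the threshold rule of [match_by_features()].
#'
#' @param table Propensity table.
#' @param cfg A [feature_match_config()].
#' @return A predicate `function(proteome_i, proteome_j)` returning a
#'   logical matrix.
#' @export
features_predicate <- function(table = default_propensity_table(),
                               cfg = feature_match_config()) {
  cache <- new.env(parent = emptyenv())
  feats <- function(p) {
    key <- p$genome_id[1]
    if (is.null(cache[[key]])) cache[[key]] <- featurize_proteome(p, table)
    cache[[key]]
  }
  function(pi, pj) match_by_features_matrix(feats(pi), feats(pj), cfg)
}

#' Classifier (ML-mode) similarity predicate
#'
#' ML-mode similarity: a pair passing the Features-mode threshold is
#' accepted directly; the random-forest classifier decides the remaining
#' pairs. Set `union_features = FALSE` for a pure-classifier predicate.
#'
#' @param model A [pair_classifier][train_pair_classifier].
#' @param table Propensity table.
#' @param match_cfg Features-mode threshold config used for the union rule.
#' @param union_features Accept Features-mode matches without consulting the
#'   forest (default `TRUE`)?
#' @return A predicate `function(proteome_i, proteome_j)`.
#' @export
classifier_predicate <- function(model, table = default_propensity_table(),
                                 match_cfg = feature_match_config(),
                                 union_features = TRUE) {
  stopifnot(inherits(model, "pair_classifier"))
  if (!identical(model$feature_layout, FEATURE_LAYOUT_VERSION)) {
    stop("feature layout mismatch: model=", model$feature_layout,
         ", featurizer=", FEATURE_LAYOUT_VERSION)
  }
  cache <- new.env(parent = emptyenv())
  feats <- function(p) {
    key <- p$genome_id[1]
    if (is.null(cache[[key]])) cache[[key]] <- featurize_proteome(p, table)
    cache[[key]]
  }
  function(pi, pj) predict_pair_matrix(model, feats(pi), feats(pj),
                                       match_cfg = match_cfg,
                                       union_features = union_features)
}
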