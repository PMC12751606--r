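#' Interaction-sampler configuration
#'
#' Controls the stochastic sampler applied to large phylogenetic-profile
#' groups. The trigger is strict: a group of exactly `trigger` members is
#' still completed; only groups with more members are sampled.
#'
#' @param trigger Group size above which sampling replaces the complete
#'   graph (default 100).
#' @param fraction Number of sublists as a fraction of the group size
#'   (default 0.9).
#' @param connectors Number of connector proteins redistributed into every
#'   sublist to maintain connectivity (default 2).
#' @param seed Optional default seed.
#' @return An object of class `ris_config`.
#' @export
ris_config <- function(trigger = 100L, fraction = 0.9, connectors = 2L,
                       seed = NULL) {
  trigger <- as.integer(trigger)
  if (trigger < 2) stop("trigger must be >= 2")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  connectors <- as.integer(connectors)
  if (connectors < 0) stop("connectors must be >= 0")
  structure(list(trigger = trigger, fraction = fraction,
                 connectors = connectors, seed = seed),
            class = "ris_config")
}

#' Stochastic interaction sampling within a profile group
#'
#' Sparsifies the complete interaction graph of a large phylogenetic-profile
#' group: the member list is shuffled, partitioned round-robin into
#' `max(2, floor(fraction * m))` disjoint sublists, `connectors` members are
#' drawn uniformly and appended to every sublist, and the union of complete
#' graphs within each sublist is emitted (deduplicated, no self-loops).
#' Groups no larger than the trigger are returned as complete graphs.
#'
#' The output is always a subset of the complete pair set on the members,
#' every member appears in at least one sublist, and the same seed yields
#' the identical edge set.
#'
#' @param members Character vector of at least 2 protein ids.
#' @param cfg A [ris_config()].
#' @param seed Seed for the shuffle and connector draw (overrides
#'   `cfg$seed`).
#' @return A data.frame of canonical undirected edges (`a`, `b`).
#' @export
ris_sample <- function(members, cfg = ris_config(), seed = cfg$seed) {
  members <- as.character(members)
  m <- length(members)
  if (m < 2) stop("need at least 2 members")
  if (anyDuplicated(members)) stop("duplicate member ids")
  if (m <= cfg$trigger) {
    return(complete_graph_edges(members))
  }
  with_seed(seed, {
    shuffled <- sample(members)
    k <- max(2L, as.integer(floor(cfg$fraction * m)))
    assignment <- rep_len(seq_len(k), m)
    sublists <- split(shuffled, assignment)
    if (cfg$connectors > 0) {
      conn <- sample(members, min(cfg$connectors, m))
      sublists <- lapply(sublists, function(s) unique(c(s, conn)))
    }
    edges <- do.call(rbind, lapply(sublists, complete_graph_edges))
    canonical_edges(edges$a, edges$b)
  })
}
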