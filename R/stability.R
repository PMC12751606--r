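# Replicate-agreement statistics for top-N node sets and rankings across
# stochastic network replicates, plus the experiment-grid orchestrator.

as_node_sets <- function(sets) {
  lapply(sets, function(s) {
    if (is.data.frame(s)) as.character(s$node) else as.character(s)
  })
}

#' Weighted global presence mean (MGP)
#'
#' Frequency-weighted mean presence of nodes across replicate top-N sets:
#' with `f_i` the fraction of replicates containing node `i` (over the union
#' of all sets), `MGP = 100 * sum(f_i^2) / sum(f_i)`. Equals 100 exactly
#' when every appearing node appears in all replicates; sparsely appearing
#' nodes are down-weighted by their own frequency. This functional form is a
#' reconstruction: it is defined here, fixed, and used consistently.
#'
#' @param sets List of node sets (character vectors or [select_top_n()]
#'   data.frames), one per replicate.
#' @return MGP in percent (0, 100].
#' @export
mgp <- function(sets) {
  sets <- as_node_sets(sets)
  if (length(sets) < 1) stop("need at least 1 replicate set")
  universe <- unique(unlist(sets))
  if (length(universe) == 0) stop("all replicate sets are empty")
  f <- vapply(universe, function(nd)
    mean(vapply(sets, function(s) nd %in% s, TRUE)), 0)
  100 * sum(f^2) / sum(f)
}

#' Pairwise Jaccard similarity of replicate top-N sets
#'
#' `J(A, B) = |A intersect B| / |A union B|` for every unordered replicate
#' pair. Two empty sets get J = 1 and the result is flagged degenerate.
#'
#' @param sets List of node sets, length >= 2.
#' @return A list with `matrix` (symmetric, unit diagonal) and `mean` (over
#'   unordered pairs); attribute `degenerate` flags empty-empty pairs.
#' @export
pairwise_jaccard <- function(sets) {
  sets <- as_node_sets(sets)
  r <- length(sets)
  if (r < 2) stop("need at least 2 replicate sets")
  m <- diag(1, r)
  degenerate <- FALSE
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0) {
        m[i, j] <- m[j, i] <- 1
        degenerate <- TRUE
      } else {
        m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  out <- list(matrix = m, mean = mean(m[upper.tri(m)]))
  attr(out, "degenerate") <- degenerate
  out
}

#' Fleiss' kappa of replicate top-N selection (adapted)
#'
#' Multi-rater chance-corrected agreement with items = nodes of the
#' universe, raters = replicates, and two categories (selected / not
#' selected). When expected agreement is 1 (every rater assigns one category
#' to every item) the kappa is returned as 1 with a degenerate flag.
#'
#' @param sets List of node sets, length >= 2.
#' @param universe Item universe; must contain the union of the sets.
#'   Defaults to that union. In pipeline use, pass all nodes of the
#'   replicate networks so that non-selection is informative.
#' @return Kappa (<= 1), possibly with attribute `degenerate`.
#' @export
fleiss_kappa <- function(sets, universe = NULL) {
  sets <- as_node_sets(sets)
  r <- length(sets)
  if (r < 2) stop("need at least 2 replicate sets")
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(as.character(universe))
  if (!all(unlist(sets) %in% universe)) {
    stop("universe must contain every selected node")
  }
  n <- length(universe)
  if (n == 0) stop("empty item universe")
  sel <- vapply(universe, function(nd)
    sum(vapply(sets, function(s) nd %in% s, TRUE)), 0L)
  nij <- cbind(selected = sel, unselected = r - sel)
  p_i <- (rowSums(nij^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(nij) / (n * r)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    return(structure(1, degenerate = TRUE))
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Kendall ratio positive of replicate rankings
#'
#' For every unordered pair of replicate rankings, the comparison is
#' restricted to nodes present in both lists; the ratio is the number of
#' concordantly ordered node pairs over the number of comparable pairs
#' (ties excluded from the denominator). The mean over replicate pairs is
#' returned. Pairs sharing fewer than 2 nodes are skipped and flagged; if
#' every pair is skipped, an error is raised.
#'
#' @param rankings List of ranked node lists (character vectors in rank
#'   order, or [select_top_n()] data.frames), length >= 2.
#' @return Mean ratio in \[0, 1\]; attribute `skipped` counts skipped pairs.
#' @export
kendall_ratio_positive <- function(rankings) {
  lists <- as_node_sets(rankings)
  r <- length(lists)
  if (r < 2) stop("need at least 2 rankings")
  ratios <- numeric(0)
  skipped <- 0L
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      shared <- intersect(lists[[i]], lists[[j]])
      if (length(shared) < 2) {
        skipped <- skipped + 1L
        next
      }
      r1 <- match(shared, lists[[i]])
      r2 <- match(shared, lists[[j]])
      s1 <- sign(outer(r1, r1, "-"))
      s2 <- sign(outer(r2, r2, "-"))
      ut <- upper.tri(s1)
      comparable <- ut & s1 != 0 & s2 != 0
      if (!any(comparable)) {
        skipped <- skipped + 1L
        next
      }
      ratios <- c(ratios, sum((s1 * s2)[comparable] > 0) / sum(comparable))
    }
  }
  if (length(ratios) == 0) stop("no replicate pair shares >= 2 ranked nodes")
  structure(mean(ratios), skipped = skipped)
}

# Two-sample Kolmogorov-Smirnov statistic: sup distance between ECDFs.
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

#' Multi-sample Kolmogorov-Smirnov distance
#'
#' The maximum over all replicate pairs of the two-sample KS statistic
#' (sup distance between empirical CDFs) of a topological metric's values.
#' Zero iff all empirical distributions coincide; the conservative max is
#' the default, the mean over pairs is available as an option.
#'
#' @param samples List of numeric samples, length >= 2, each non-empty.
#' @param aggregate `"max"` (default) or `"mean"` over replicate pairs.
#' @return KS distance in \[0, 1\].
#' @export
ks_multi <- function(samples, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  r <- length(samples)
  if (r < 2) stop("need at least 2 samples")
  if (any(vapply(samples, length, 0L) == 0)) stop("empty sample")
  ds <- numeric(0)
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      ds <- c(ds, ks_statistic(samples[[i]], samples[[j]]))
    }
  }
  if (aggregate == "max") max(ds) else mean(ds)
}

#' Replicate-stability statistics for one configuration
#'
#' Computes the full agreement suite (MGP, mean pairwise Jaccard, adapted
#' Fleiss' kappa, Kendall ratio positive, multi-sample KS distance) from a
#' list of replicate networks under one (metric, top-N) setting.
#'
#' @param networks List of `ppi_network` replicates (length >= 2).
#' @param metric Centrality metric for top-N selection.
#' @param top_n Number of top nodes to compare.
#' @return A one-row data.frame with the five statistics and the replicate
#'   count.
#' @export
stability_statistics <- function(networks, metric = "degree", top_n = 100L) {
  stopifnot(length(networks) >= 2)
  cmaps <- lapply(networks, compute_centrality, metric = metric)
  tops <- lapply(cmaps, select_top_n, n = top_n)
  universe <- unique(unlist(lapply(networks, function(nw) nw$nodes)))
  data.frame(
    metric = metric,
    top_n = as.integer(top_n),
    replicates = length(networks),
    mgp = mgp(tops),
    jaccard_mean = pairwise_jaccard(tops)$mean,
    fleiss_kappa = as.numeric(fleiss_kappa(tops, universe = universe)),
    kendall_rp = as.numeric(kendall_ratio_positive(tops)),
    ks_multi = ks_multi(lapply(cmaps, as.numeric)),
    stringsAsFactors = FALSE
  )
}

#' Expand a stability experiment grid
#'
#' One row per experimental configuration: the cross product of operational
#' modes, input-file counts, top-N values and centrality metrics. With the
#' full-scale settings (2 modes, file counts 10-50 in steps of 10, six top-N
#' values, three metrics) this yields 180 configurations.
#'
#' @param modes Character vector of operational modes.
#' @param n_files Integer vector of input-file counts.
#' @param top_n Integer vector of top-N values.
#' @param metrics Character vector of centrality metrics.
#' @return A data.frame with one row per configuration.
#' @export
stability_grid <- function(modes = c("features", "ml"),
                           n_files = seq(10L, 50L, by = 10L),
                           top_n = c(10L, 25L, 50L, 100L, 150L, 200L),
                           metrics = c("degree", "betweenness", "bridging")) {
  expand.grid(mode = modes, n_files = n_files, top_n = top_n,
              metric = metrics, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' Run a replicate-stability experiment over a configuration grid
#'
#' For each grid configuration, `replicates` networks are generated through
#' the caller-supplied pipeline handle (seeded deterministically from the
#' master seed), the top-N nodes per the configuration's metric are
#' extracted, and the full agreement suite is computed. A failing replicate
#' flags its configuration; the remaining configurations proceed.
#'
#' @param network_fn Pipeline handle
#'   `function(mode, n_files, replicate_seed)` returning a `ppi_network`.
#' @param grid A [stability_grid()] data.frame.
#' @param replicates Replicates per configuration (>= 2).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param out_dir Optional directory for the configuration-level CSV report
#'   and per-replicate top-N CSVs.
#' @return A data.frame of class `stability_report`: the grid with the five
#'   statistics, a `status` column, and the seed derivation recorded in
#'   attributes.
#' @export
run_stability_experiment <- function(network_fn, grid = stability_grid(),
                                     replicates = 50L, seed = 1L,
                                     out_dir = NULL) {
  stopifnot(is.function(network_fn), replicates >= 2)
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cfg <- grid[ci, ]
    res <- tryCatch({
      nets <- lapply(seq_len(replicates), function(r) {
        network_fn(cfg$mode, cfg$n_files, derive_seed(seed, ci, r))
      })
      stats <- stability_statistics(nets, metric = cfg$metric,
                                    top_n = cfg$top_n)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (r in seq_along(nets)) {
          top <- select_top_n(compute_centrality(nets[[r]],
                                                 metric = cfg$metric),
                              cfg$top_n)
          write_top_n_csv(top, file.path(out_dir, sprintf(
            "top_%s_%s_n%d_top%d_rep%02d.csv", cfg$mode, cfg$metric,
            cfg$n_files, cfg$top_n, r)))
        }
      }
      cbind(cfg[c("mode", "n_files")], stats, status = "ok")
    }, error = function(e) {
      cbind(cfg[c("mode", "n_files")],
            data.frame(metric = cfg$metric, top_n = cfg$top_n,
                       replicates = replicates, mgp = NA_real_,
                       jaccard_mean = NA_real_, fleiss_kappa = NA_real_,
                       kendall_rp = NA_real_, ks_multi = NA_real_,
                       stringsAsFactors = FALSE),
            status = paste("failed:", conditionMessage(e)))
    })
    rows[[ci]] <- res
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "seed") <- seed
  attr(report, "seed_derivation") <-
    "replicate_seed = derive_seed(master, config_index, replicate)"
  class(report) <- c("stability_report", "data.frame")
  if (!is.null(out_dir)) {
    write.csv(report, file.path(out_dir, "stability_report.csv"),
              row.names = FALSE)
  }
  report
}
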