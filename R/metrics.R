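#' Node centrality of an interaction network
#'
#' Supported metrics: `degree` (incident-edge count, identifying hubs),
#' `betweenness` (unnormalized shortest-path counts with even splitting over
#' equal-length paths, identifying bottlenecks), and `bridging`
#' (betweenness multiplied by the bridging coefficient
#' `b(v) = (1/deg(v)) / sum_u 1/deg(u)` over the neighbors `u` of `v`,
#' identifying connectors between communities). Isolated nodes get bridging
#' centrality 0.
#'
#' @param network A `ppi_network` or an `igraph` graph.
#' @param metric One of `"degree"`, `"betweenness"`, `"bridging"`.
#' @return Named numeric vector over all network nodes, with attribute
#'   `metric`.
#' @export
compute_centrality <- function(network,
                               metric = c("degree", "betweenness", "bridging")) {
  metric <- match.arg(metric)
  g <- if (inherits(network, "ppi_network")) as_igraph(network) else network
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g)
  values <- switch(metric,
    degree = deg,
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE),
    bridging = {
      btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
      bcoef <- vapply(seq_along(deg), function(v) {
        if (deg[v] == 0) return(0)
        nb <- as.integer(igraph::neighbors(g, v))
        denom <- sum(1 / deg[nb])
        if (denom == 0) 0 else (1 / deg[v]) / denom
      }, 0)
      btw * bcoef
    })
  out <- setNames(as.numeric(values), igraph::V(g)$name)
  attr(out, "metric") <- metric
  out
}

#' Select the top-N nodes of a centrality map
#'
#' Nodes are ranked by centrality value descending; ties are broken by node
#' id ascending, so the ranking is deterministic and replicate-comparable.
#'
#' @param cmap Named numeric vector (e.g. from [compute_centrality()]).
#' @param n Number of nodes to select (>= 1); capped at the node count.
#' @return A data.frame with columns `rank`, `node`, `value`.
#' @export
select_top_n <- function(cmap, n) {
  if (n < 1) stop("n must be >= 1")
  ids <- names(cmap)
  ord <- order(-as.numeric(cmap), ids)
  take <- head(ord, min(n, length(cmap)))
  data.frame(rank = seq_along(take), node = ids[take],
             value = as.numeric(cmap)[take], stringsAsFactors = FALSE)
}

#' Write a top-N ranking as CSV
#'
#' @param top A [select_top_n()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_top_n_csv <- function(top, path) {
  write.csv(top, path, row.names = FALSE)
  invisible(path)
}
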