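# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(aa20, n, replace = TRUE),
                                    collapse = "")

# A one-scale toy propensity table with value `value` for every residue.
toy_table <- function(value = 1, scale = "TOY") {
  m <- matrix(value, nrow = 1, ncol = 20, dimnames = list(scale, aa20))
  class(m) <- c("propensity_table", "matrix", "array")
  m
}

write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# Proteome data.frame built directly (no file round trip).
make_proteome <- function(ids, sequences, genome_id) {
  df <- data.frame(id = ids, sequence = sequences, genome_id = genome_id,
                   position = seq_along(ids) - 1L, description = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("proteome", "data.frame")
  df
}

# Similarity predicate from an explicit lookup of similar id pairs.
pairs_predicate <- function(similar_pairs) {
  keys <- c(paste(similar_pairs$a, similar_pairs$b),
            paste(similar_pairs$b, similar_pairs$a))
  function(pi, pj) {
    m <- outer(pi$id, pj$id, function(x, y) paste(x, y) %in% keys)
    dimnames(m) <- list(pi$id, pj$id)
    m
  }
}

# Brute-force betweenness oracle: BFS shortest-path counting over all
# ordered source-target pairs, even splitting over equal-length paths.
bf_betweenness <- function(nodes, edges) {
  adj <- lapply(setNames(nodes, nodes), function(v)
    unique(c(edges$b[edges$a == v], edges$a[edges$b == v])))
  btw <- setNames(numeric(length(nodes)), nodes)
  paths_between <- function(s, t) {
    # enumerate all shortest s-t paths by BFS layering
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0 && !is.finite(dist[t])) {
      nxt <- character(0)
      for (v in frontier) for (u in adj[[v]]) {
        if (!is.finite(dist[u])) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
      }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) return(list(path))
      do.call(c, lapply(adj[[v]][dist[adj[[v]]] == dist[v] + 1],
                        function(u) grow(c(path, u))))
    }
    grow(s)
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      ps <- paths_between(nodes[i], nodes[j])
      if (length(ps) == 0) next
      for (p in ps) {
        inner <- setdiff(p, c(nodes[i], nodes[j]))
        btw[inner] <- btw[inner] + 1 / length(ps)
      }
    }
  }
  btw
}

# Synthetic stochastic replicate network: three sampled profile groups plus
# a deterministic degree-gradient core whose upper half also receives
# sampled noise. Emulates the ML-mode regime where sampling noise perturbs
# hub identity most at small top-N.
make_ris_replicate <- function(seed) {
  core <- sprintf("s%03d", 1:260)
  groups <- list(sprintf("ga%03d", 1:120), sprintf("gb%03d", 1:120),
                 sprintf("gc%03d", 1:120), core[111:260])
  edges <- do.call(rbind, lapply(seq_along(groups), function(k)
    ris_sample(groups[[k]], ris_config(trigger = 100), seed = seed * 10 + k)))
  ca <- character(0); cb <- character(0)
  for (i in 1:259) {
    k <- min(3 + i %/% 12, 24)
    j <- seq(i + 1, min(260, i + k))
    ca <- c(ca, rep(core[i], length(j))); cb <- c(cb, core[j])
  }
  edges <- rbind(edges[, c("a", "b")], data.frame(a = ca, b = cb))
  edges$evidence <- "profile"
  assemble_network(list(edges), c(unlist(groups[1:3]), core),
                   genome_id = "replicate")
}

# Small simulated proteome set reused by pipeline-level tests.
smoke_simulation <- function(seed = 11, n_genomes = 3, genes = 40,
                             identity = 0.9) {
  simulate_proteome_set(simulation_config(n_genomes = n_genomes,
                                          genes_per_genome = genes,
                                          family_identity = identity,
                                          seed = seed))
}
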