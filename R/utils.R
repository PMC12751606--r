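# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package go
# through this, so results are a pure function of (inputs, config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic derivation of stage/replicate seeds from a master seed.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x)
}

# Canonical undirected form of an edge table: endpoints sorted within each
# pair (string order), self-loops dropped, duplicates removed.
canonical_edges <- function(a, b, drop_self = TRUE) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (length(a) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  keep <- if (drop_self) a != b else rep(TRUE, length(a))
  key <- paste(a[keep], b[keep], sep = "\r")
  dup <- duplicated(key)
  data.frame(a = a[keep][!dup], b = b[keep][!dup], stringsAsFactors = FALSE)
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  paste(edges$a, edges$b, sep = "\r")
}

# Complete undirected graph on a set of node ids.
complete_graph_edges <- function(members) {
  members <- as.character(members)
  m <- length(members)
  if (m < 2) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- combn(m, 2)
  canonical_edges(members[idx[1, ]], members[idx[2, ]])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
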