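#' Read a proteome from a multi-FASTA file
#'
#' Reads one genome's protein complement from a multi-FASTA file. Record
#' order in the file is taken to define gene order on the chromosome: the
#' `position` column numbers records 0..n-1 in file order, and the conserved
#' gene-neighborhood evidence relies on it. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as a
#' description but otherwise unused.
#'
#' Non-standard residue letters (B, J, O, U, X, Z) are accepted with a
#' warning; any non-letter character in a sequence is an error.
#'
#' @param path Path to a protein multi-FASTA file.
#' @param genome_id Genome identifier attached to every record. Defaults to
#'   the file name without extension.
#' @return A `data.frame` of class `proteome` with columns `id`, `sequence`,
#'   `genome_id`, `position` (0-based) and `description`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 first", "ACDEF", ">p2", "GHIKL"), fa)
#' read_proteome_fasta(fa, "toy")
#' @export
read_proteome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- tools::file_path_sans_ext(basename(path))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(as.character(seqs))
  bad <- !grepl("^[A-Z]+$", sequences)
  if (any(bad)) {
    stop("non-letter residue characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  nonstd <- grepl(paste0("[", paste(AA_NONSTANDARD, collapse = ""), "]"),
                  sequences)
  if (any(nonstd)) {
    warning("non-standard residues (", paste(AA_NONSTANDARD, collapse = ""),
            ") in record(s): ", paste(ids[nonstd], collapse = ", "),
            "; they contribute zero to propensity sums")
  }
  out <- data.frame(id = unname(ids),
                    sequence = unname(sequences),
                    genome_id = genome_id,
                    position = seq_along(ids) - 1L,
                    description = unname(desc),
                    stringsAsFactors = FALSE)
  class(out) <- c("proteome", "data.frame")
  out
}

#' Read an amino-acid propensity table
#'
#' Parses a whitespace/tab-delimited propensity file: a header row naming the
#' 20 standard amino-acid columns, then one row per physicochemical scale
#' (scale name followed by 20 numbers). Row order is preserved because it
#' fixes the layout of the 60-value feature vector.
#'
#' @param path Path to the propensity file.
#' @return A numeric matrix (scales x 20 residues) of class
#'   `propensity_table`, rows in file order, columns the standard amino
#'   acids.
#' @seealso [default_propensity_table()]
#' @export
read_propensity_table <- function(path) {
  if (!file.exists(path)) stop("propensity file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("propensity file needs a header and >= 1 scale row")
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1]]
  # header may carry a leading label for the scale-name column
  if (length(header) == 21) header <- header[-1]
  aa_cols <- toupper(header)
  if (length(aa_cols) != 20 || !setequal(aa_cols, AA20)) {
    stop("propensity header must name the 20 standard amino acids; got: ",
         paste(header, collapse = " "))
  }
  rows <- toks[-1]
  values <- matrix(NA_real_, nrow = length(rows), ncol = 20,
                   dimnames = list(NULL, aa_cols))
  scales <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 21) {
      stop("propensity row ", i, " ('", r[1], "') has ", length(r) - 1,
           " values; expected 20")
    }
    scales[i] <- r[1]
    num <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(num)) {
      stop("unparseable number in propensity row ", i, " ('", r[1],
           "'), column ", which(is.na(num))[1])
    }
    values[i, ] <- num
  }
  if (anyDuplicated(scales)) stop("duplicate scale names in propensity file")
  values <- values[, AA20, drop = FALSE]
  rownames(values) <- scales
  class(values) <- c("propensity_table", "matrix", "array")
  values
}

#' Bundled 10-scale propensity table
#'
#' The propensity table shipped with the package: indicator scales for basic,
#' acidic, polar and non-polar residues, monoisotopic and average residue
#' masses, and four AAindex-style numeric scales (PARJ860101, JOND750101,
#' EISD840101, JURD980101). The exact values are configuration, not ground
#' truth: any table in the same dialect can be substituted via
#' [read_propensity_table()].
#'
#' @return A `propensity_table` with 10 scales x 20 residues.
#' @export
default_propensity_table <- function() {
  read_propensity_table(system.file("extdata", "propensity.tsv",
                                    package = "gcppi", mustWork = TRUE))
}

dot_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write an interaction network in DOT format
#'
#' Emits an undirected `graph` document with quoted, sanitized node ids
#' (non-alphanumeric characters replaced by `_`). Edges are written in
#' canonical sorted order with their evidence labels, so two equal networks
#' produce byte-identical files.
#'
#' @param network A [ppi_network] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_network_dot()]
#' @export
write_network_dot <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  edges <- network$edges
  name <- dot_sanitize(network$genome_id %||% "network")
  lines <- c(sprintf("graph \"%s\" {", name))
  endpoints <- character(0)
  if (nrow(edges) > 0) {
    a <- dot_sanitize(edges$a)
    b <- dot_sanitize(edges$b)
    ev <- if (!is.null(edges$evidence)) edges$evidence else rep("", nrow(edges))
    ord <- order(a, b)
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [evidence=\"%s\"];",
                              a[ord], b[ord], ev[ord]))
    endpoints <- unique(c(a, b))
  }
  isolated <- sort(setdiff(dot_sanitize(network$nodes), endpoints))
  if (length(isolated) > 0) {
    lines <- c(lines, sprintf("  \"%s\";", isolated))
  }
  lines <- c(lines, "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a DOT file written by [write_network_dot()]
#'
#' A parser for the package's own undirected DOT dialect (one edge statement
#' per line with an optional `evidence` attribute). It is meant for
#' round-tripping package output, not as a general DOT reader.
#'
#' @param path Path to a DOT file.
#' @return A [ppi_network] object.
#' @export
read_network_dot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty DOT file: ", path)
  m <- regmatches(lines[1], regexec("^graph\\s+\"([^\"]*)\"", lines[1]))[[1]]
  genome_id <- if (length(m) == 2) m[2] else "network"
  edge_re <- "^\\s*\"([^\"]+)\"\\s*--\\s*\"([^\"]+)\"(\\s*\\[evidence=\"([^\"]*)\"\\])?\\s*;"
  node_re <- "^\\s*\"([^\"]+)\"\\s*;"
  a <- character(0); b <- character(0); ev <- character(0)
  nodes <- character(0)
  for (ln in lines[-1]) {
    me <- regmatches(ln, regexec(edge_re, ln))[[1]]
    if (length(me) > 0) {
      a <- c(a, me[2]); b <- c(b, me[3])
      ev <- c(ev, if (length(me) >= 5) me[5] else "")
      next
    }
    mn <- regmatches(ln, regexec(node_re, ln))[[1]]
    if (length(mn) > 0) nodes <- c(nodes, mn[2])
  }
  aa <- pmin(a, b); bb <- pmax(a, b)
  keep <- aa != bb
  key <- paste(aa[keep], bb[keep], sep = "\r")
  first <- !duplicated(key)
  edges <- data.frame(a = aa[keep][first], b = bb[keep][first],
                      evidence = ev[keep][first], stringsAsFactors = FALSE)
  new_ppi_network(genome_id = genome_id,
                  edges = edges,
                  nodes = unique(c(nodes, edges$a, edges$b)))
}

#' Read a two-column edge list
#'
#' Reads a delimited two-column edge list (TSV or whitespace separated).
#' Records are kept in file order and in their native orientation; the
#' `directed` flag records the source's convention (e.g. a reference that
#' lists A-B and B-A as two records).
#'
#' @param path Path to the edge list.
#' @param directed Logical: does the source count A-B and B-A as distinct?
#' @param header Logical: skip a header row?
#' @return An object of class `edge_set`: a list with `records` (data.frame
#'   `a`, `b` in file order) and `directed`.
#' @export
read_edge_list <- function(path, directed = FALSE, header = FALSE) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) > 0) lines <- lines[-1]
  if (length(lines) == 0) {
    return(edge_set(data.frame(a = character(0), b = character(0),
                               stringsAsFactors = FALSE), directed))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  nc <- lengths(toks)
  if (any(nc != 2)) {
    stop("edge list row ", which(nc != 2)[1] + if (header) 1L else 0L,
         " has ", nc[nc != 2][1], " columns; expected 2")
  }
  edge_set(data.frame(a = vapply(toks, `[`, "", 1),
                      b = vapply(toks, `[`, "", 2),
                      stringsAsFactors = FALSE), directed)
}

#' Construct an edge set
#'
#' @param records A data.frame with columns `a` and `b`, records in source
#'   order and native orientation.
#' @param directed Logical flag describing the source's convention.
#' @return An object of class `edge_set`.
#' @export
edge_set <- function(records, directed = FALSE) {
  stopifnot(is.data.frame(records), all(c("a", "b") %in% names(records)))
  structure(list(records = records[, c("a", "b")], directed = directed),
            class = "edge_set")
}

#' Unique undirected pairs of an edge set
#'
#' Normalizes to canonical undirected form: (a,b) and (b,a) collapse to one
#' key, self-loops are dropped, duplicates removed.
#'
#' @param x An `edge_set`, `ppi_network`, or data.frame with columns `a`,`b`.
#' @return A data.frame of canonical unique pairs.
#' @export
unique_undirected <- function(x) {
  df <- if (inherits(x, "edge_set")) x$records
        else if (inherits(x, "ppi_network")) x$edges
        else x
  canonical_edges(df$a, df$b)
}

#' @export
print.edge_set <- function(x, ...) {
  cat("<edge_set> ", nrow(x$records), " record(s), ",
      if (x$directed) "directed" else "undirected", " source, ",
      nrow(unique_undirected(x)), " unique undirected pair(s)\n", sep = "")
  invisible(x)
}
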