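#' Compare a predicted network against a reference edge list
#'
#' Reimplements the `count_intersect` comparison arithmetic. The query is
#' reduced to its unique undirected pairs. The intersection is counted at
#' the *record* level of the reference in its native representation: a
#' reference that lists each interaction in both orientations (A-B and B-A)
#' contributes two records per matched pair. This convention reproduces the
#' self-comparison arithmetic of such doubled references (ratio 0.5,
#' proportion 2.0); the normalized both-undirected variant, which is the
#' recommended reading, is reported alongside.
#'
#' @param query A `ppi_network`, `edge_set`, or data.frame of edges.
#' @param reference An [edge_set()]; must be non-empty.
#' @return An object of class `comparison_report`: a list with
#'   `query_unique`, `reference_unique`, `intersect_count` (record-level),
#'   `unique_intersect_ratio` (= query_unique / intersect_count; `NA` and
#'   flagged when the intersection is empty), `reference_proportion`
#'   (= intersect_count / reference_unique), and the normalized variants
#'   `intersect_unique`, `ratio_normalized`, `proportion_normalized`.
#' @export
count_intersect <- function(query, reference) {
  stopifnot(inherits(reference, "edge_set"))
  if (nrow(reference$records) == 0) stop("empty reference edge set")
  q <- unique_undirected(query)
  qkeys <- edge_keys(q)
  ref_records <- reference$records
  aa <- pmin(ref_records$a, ref_records$b)
  bb <- pmax(ref_records$a, ref_records$b)
  keep <- aa != bb
  rec_keys <- paste(aa[keep], bb[keep], sep = "\r")
  ref_unique_keys <- unique(rec_keys)
  intersect_count <- sum(rec_keys %in% qkeys)
  intersect_unique <- sum(ref_unique_keys %in% qkeys)
  ratio <- if (intersect_count > 0) nrow(q) / intersect_count else NA_real_
  structure(list(
    query_unique = nrow(q),
    reference_unique = length(ref_unique_keys),
    intersect_count = intersect_count,
    unique_intersect_ratio = ratio,
    reference_proportion = intersect_count / length(ref_unique_keys),
    intersect_unique = intersect_unique,
    ratio_normalized = if (intersect_unique > 0) nrow(q) / intersect_unique
                       else NA_real_,
    proportion_normalized = intersect_unique / length(ref_unique_keys),
    ratio_undefined = intersect_count == 0
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n",
      "  query unique pairs:     ", x$query_unique, "\n",
      "  reference unique pairs: ", x$reference_unique, "\n",
      "  intersect (records):    ", x$intersect_count, "\n",
      "  unique/intersect ratio: ", format(x$unique_intersect_ratio), "\n",
      "  reference proportion:   ", format(x$reference_proportion), "\n",
      "  normalized: intersect=", x$intersect_unique,
      " ratio=", format(x$ratio_normalized),
      " proportion=", format(x$proportion_normalized), "\n", sep = "")
  if (x$ratio_undefined) cat("  (ratio undefined: empty intersection)\n")
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' @param report A [count_intersect()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_comparison_csv <- function(report, path) {
  df <- data.frame(
    query_unique = report$query_unique,
    reference_unique = report$reference_unique,
    intersect_count = report$intersect_count,
    unique_intersect_ratio = report$unique_intersect_ratio,
    reference_proportion = report$reference_proportion,
    intersect_unique = report$intersect_unique,
    ratio_normalized = report$ratio_normalized,
    proportion_normalized = report$proportion_normalized
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
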