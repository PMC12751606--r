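#' Split a sequence into start, middle and end regions
#'
#' Both flanking regions get `floor(n/3)` residues; the middle absorbs the
#' remainder, so `start + middle + end` always reconstructs the input.
#'
#' @param sequence Non-empty amino-acid string.
#' @return A named character vector with elements `start`, `middle`, `end`.
#' @examples
#' segment_regions("ACDEFGHIKL") # 3 / 4 / 3
#' @export
segment_regions <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  k <- n %/% 3
  c(start = substr(sequence, 1, k),
    middle = substr(sequence, k + 1, n - k),
    end = substr(sequence, n - k + 1, n))
}

#' Compute the 60-value propensity descriptor of a protein
#'
#' For each scale of the propensity table (in table row order) the raw sum of
#' per-residue scale values is computed over the whole sequence and over its
#' start, middle and end regions (40 values), followed by the counts of the
#' 20 standard amino acids in alphabetical order (20 values). Sums are plain
#' (not length-normalized). Non-standard residues (B, J, O, U, X, Z)
#' contribute zero to every scale sum and are excluded from the counts; a
#' warning is raised when they occur.
#'
#' @param sequence Non-empty amino-acid string.
#' @param table A [propensity_table][read_propensity_table]. Defaults to the
#'   bundled 10-scale table.
#' @return Named numeric vector of length `4 * nrow(table) + 20` (60 for the
#'   default table), with attribute `layout` recording the feature-layout
#'   version.
#' @export
featurize <- function(sequence, table = default_propensity_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty sequence")
  res <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(unique(res), c(AA20, AA_NONSTANDARD))
  if (length(unknown) > 0) {
    stop("residue(s) not in propensity table and not a recognized ",
         "non-standard letter: ", paste(unknown, collapse = ", "))
  }
  if (any(res %in% AA_NONSTANDARD)) {
    warning("non-standard residue(s) contribute zero to scale sums and are ",
            "excluded from counts")
  }
  n <- length(res)
  k <- n %/% 3
  region <- rep.int(2L, n)              # middle
  if (k > 0) {
    region[seq_len(k)] <- 1L            # start
    region[(n - k + 1):n] <- 3L         # end
  }
  scales <- rownames(table)
  values <- numeric(0)
  for (s in scales) {
    v <- unname(table[s, ])[match(res, AA20)]
    v[is.na(v)] <- 0                    # non-standard residues
    values <- c(values,
                sum(v),
                sum(v[region == 1L]),
                sum(v[region == 2L]),
                sum(v[region == 3L]))
  }
  counts <- as.numeric(table(factor(res, levels = AA20)))
  out <- c(values, counts)
  names(out) <- c(as.vector(t(outer(scales, c("whole", "start", "middle", "end"),
                                    paste, sep = "_"))),
                  paste0("count_", AA20))
  attr(out, "layout") <- FEATURE_LAYOUT_VERSION
  out
}

#' Featurize every protein of a proteome
#'
#' @param proteome A [proteome][read_proteome_fasta] data.frame.
#' @param table Propensity table.
#' @return Numeric matrix, one row per protein (rownames = protein ids),
#'   columns in the fixed 60-feature layout.
#' @export
featurize_proteome <- function(proteome, table = default_propensity_table()) {
  stopifnot(is.data.frame(proteome), nrow(proteome) > 0)
  rows <- suppressWarnings(
    lapply(proteome$sequence, featurize, table = table)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- proteome$id
  attr(out, "layout") <- FEATURE_LAYOUT_VERSION
  out
}

#' Write a per-protein feature table as CSV
#'
#' One row per protein: the protein id followed by the 60 feature columns.
#'
#' @param features Matrix from [featurize_proteome()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_csv <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
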