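#' Configuration for threshold-based feature matching
#'
#' Two proteins are called similar in Features mode when at least
#' `min_matches` of the 60 feature coordinates differ by at most `tolerance`
#' units. The defaults (25 matches, tolerance 1) are the operational
#' defaults; the tolerance may be set to 2 for a looser match.
#'
#' @param min_matches Integer in 1..60, default 25.
#' @param tolerance Positive real, default 1.
#' @return An object of class `feature_match_config`.
#' @export
feature_match_config <- function(min_matches = 25L, tolerance = 1) {
  min_matches <- as.integer(min_matches)
  if (is.na(min_matches) || min_matches < 1 || min_matches > 60) {
    stop("min_matches must be in 1..60")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  structure(list(min_matches = min_matches, tolerance = tolerance),
            class = "feature_match_config")
}

#' Features-mode similarity decision
#'
#' @param a,b Feature vectors of equal length (normally 60).
#' @param cfg A [feature_match_config()].
#' @return Logical: are the proteins similar?
#' @export
match_by_features <- function(a, b, cfg = feature_match_config()) {
  if (length(a) != length(b)) {
    stop("feature vectors differ in length (", length(a), " vs ",
         length(b), ")")
  }
  sum(abs(a - b) <= cfg$tolerance) >= cfg$min_matches
}

# All-pairs Features-mode similarity between two feature matrices.
# Returns a logical matrix nrow(A) x nrow(B).
match_by_features_matrix <- function(A, B, cfg = feature_match_config()) {
  stopifnot(ncol(A) == ncol(B))
  counts <- matrix(0L, nrow(A), nrow(B))
  for (j in seq_len(ncol(A))) {
    counts <- counts + (abs(outer(A[, j], B[, j], "-")) <= cfg$tolerance)
  }
  out <- counts >= cfg$min_matches
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' Encode a protein pair for classification
#'
#' The default encoding is the element-wise absolute difference of the two
#' feature vectors: symmetric by construction and aligned with the
#' per-coordinate comparison of Features mode. A concatenation encoding
#' (a then b; not symmetric) is available as a non-default option.
#'
#' @param a,b Feature vectors of equal length.
#' @param method `"absdiff"` (default) or `"concat"`.
#' @return Numeric encoding vector.
#' @export
encode_pair <- function(a, b, method = c("absdiff", "concat")) {
  method <- match.arg(method)
  if (length(a) != length(b)) {
    stop("feature vectors differ in length (", length(a), " vs ",
         length(b), ")")
  }
  if (method == "absdiff") abs(a - b) else c(a, b)
}

#' Build a labeled training table of protein pairs
#'
#' Encodes labeled pairs with [encode_pair()] and applies the
#' negative-to-positive ratio protocol: when more negatives are available
#' than `ratio` times the number of positives, negatives are downsampled
#' (seeded, without replacement). Rows are ordered with all negatives
#' preceding all positives.
#'
#' @param pairs A data.frame with columns `seq_a`, `seq_b` and `label`
#'   (logical, or character `"positive"`/`"negative"`), or columns
#'   `features_a`/`features_b` holding pre-computed feature rows via the
#'   `features_a`/`features_b` arguments.
#' @param table Propensity table used to featurize sequences.
#' @param ratio Target negative:positive ratio (integer >= 1, default 3).
#' @param seed Seed for the negative downsampling.
#' @param encoding Pair encoding method (see [encode_pair()]).
#' @param features_a,features_b Optional pre-computed feature matrices (one
#'   row per pair, aligned with `pairs$label`), bypassing featurization.
#' @return An object of class `pair_table`: list with `x` (encoded matrix,
#'   negatives first), `y` (factor negative/positive), `n_negative`,
#'   `n_positive`, `encoding`, `layout`.
#' @export
build_pair_table <- function(pairs = NULL, table = default_propensity_table(),
                             ratio = 3L, seed = 1L,
                             encoding = c("absdiff", "concat"),
                             features_a = NULL, features_b = NULL) {
  encoding <- match.arg(encoding)
  if (ratio < 1) stop("ratio must be >= 1")
  if (is.null(features_a)) {
    stopifnot(is.data.frame(pairs),
              all(c("seq_a", "seq_b", "label") %in% names(pairs)))
    features_a <- do.call(rbind, suppressWarnings(
      lapply(pairs$seq_a, featurize, table = table)))
    features_b <- do.call(rbind, suppressWarnings(
      lapply(pairs$seq_b, featurize, table = table)))
    label <- pairs$label
  } else {
    stopifnot(!is.null(features_b), nrow(features_a) == nrow(features_b))
    label <- pairs$label
  }
  if (is.character(label)) label <- label == "positive"
  pos_idx <- which(label)
  neg_idx <- which(!label)
  if (length(pos_idx) == 0) stop("no positive pairs")
  if (length(neg_idx) == 0) stop("no negative pairs")
  n_keep <- as.integer(ratio) * length(pos_idx)
  if (length(neg_idx) > n_keep) {
    neg_idx <- with_seed(seed, sort(sample(neg_idx, n_keep)))
  } else if (length(neg_idx) < n_keep) {
    warning("only ", length(neg_idx), " negatives available for requested ",
            "ratio ", ratio, ":1; keeping all")
  }
  enc <- function(i) encode_pair(features_a[i, ], features_b[i, ],
                                 method = encoding)
  x <- rbind(do.call(rbind, lapply(neg_idx, enc)),
             do.call(rbind, lapply(pos_idx, enc)))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(rep(c("negative", "positive"),
                  c(length(neg_idx), length(pos_idx))),
              levels = c("negative", "positive"))
  structure(list(x = x, y = y,
                 n_negative = length(neg_idx),
                 n_positive = length(pos_idx),
                 encoding = encoding,
                 layout = FEATURE_LAYOUT_VERSION),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("<pair_table> ", x$n_negative, " negative + ", x$n_positive,
      " positive pairs (negatives first), encoding=", x$encoding, "\n",
      sep = "")
  invisible(x)
}

#' Write a pair table as ARFF
#'
#' Numeric attributes `f1..fK`, class attribute `{negative,positive}` last;
#' data rows keep the negatives-before-positives ordering.
#'
#' @param pair_table A [build_pair_table()] result.
#' @param path Output path.
#' @param relation ARFF relation name.
#' @return Invisibly, `path`.
#' @export
write_pair_arff <- function(pair_table, path, relation = "protein_pairs") {
  stopifnot(inherits(pair_table, "pair_table"))
  lines <- c(paste("@relation", relation),
             "",
             paste("@attribute", colnames(pair_table$x), "numeric"),
             "@attribute class {negative,positive}",
             "",
             "@data",
             paste0(apply(pair_table$x, 1, paste, collapse = ","), ",",
                    as.character(pair_table$y)))
  writeLines(lines, path)
  invisible(path)
}

#' Random-forest configuration for the pair classifier
#'
#' Defaults follow the custom hyperparameter set used operationally: 500
#' trees, maximum depth 30, 10 candidate feature subsets per split, bagging
#' ratio 1.0, minimum one sample per leaf, and a 3:1 negative:positive
#' training ratio.
#'
#' @param n_tree Number of trees (default 500).
#' @param max_depth Maximum tree depth (default 30).
#' @param n_trial Candidate features per split (default 10).
#' @param bagging_ratio Bootstrap sample fraction (default 1.0).
#' @param min_region_samples Minimum samples per leaf (default 1).
#' @param negative_ratio Negative:positive training ratio (default 3).
#' @param seed Training seed (recorded in any serialized model).
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_tree = 500L, max_depth = 30L, n_trial = 10L,
                          bagging_ratio = 1.0, min_region_samples = 1L,
                          negative_ratio = 3L, seed = 1L) {
  vals <- list(n_tree = as.integer(n_tree), max_depth = as.integer(max_depth),
               n_trial = as.integer(n_trial), bagging_ratio = bagging_ratio,
               min_region_samples = as.integer(min_region_samples),
               negative_ratio = as.integer(negative_ratio),
               seed = as.integer(seed))
  if (any(vapply(vals, function(v) v <= 0, TRUE))) {
    stop("all forest_config values must be positive")
  }
  structure(vals, class = "forest_config")
}

#' Train the random-forest pair classifier
#'
#' Fits a probability forest on an encoded pair table. The returned model
#' records its configuration and the feature-layout version; prediction
#' refuses to run against a different layout. Training is seeded and
#' reproducible; [save_pair_classifier()] / [load_pair_classifier()]
#' round-trip the model through a single file.
#'
#' @param pair_table A [build_pair_table()] result with both classes.
#' @param config A [forest_config()].
#' @return An object of class `pair_classifier`.
#' @export
train_pair_classifier <- function(pair_table, config = forest_config()) {
  stopifnot(inherits(pair_table, "pair_table"))
  if (nrow(pair_table$x) == 0) stop("empty pair table")
  if (nlevels(droplevels(pair_table$y)) < 2) {
    stop("pair table must contain both classes")
  }
  df <- data.frame(pair_table$x, class = pair_table$y)
  forest <- ranger::ranger(
    dependent.variable.name = "class",
    data = df,
    num.trees = config$n_tree,
    max.depth = config$max_depth,
    mtry = min(config$n_trial, ncol(pair_table$x)),
    sample.fraction = config$bagging_ratio,
    replace = TRUE,
    min.node.size = config$min_region_samples,
    probability = TRUE,
    seed = config$seed,
    num.threads = 1
  )
  structure(list(forest = forest,
                 config = config,
                 encoding = pair_table$encoding,
                 feature_layout = pair_table$layout,
                 n_features = ncol(pair_table$x)),
            class = "pair_classifier")
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat("<pair_classifier> random forest, ", x$config$n_tree, " trees, depth <= ",
      x$config$max_depth, ", encoding=", x$encoding,
      ", layout=", x$feature_layout, "\n", sep = "")
  invisible(x)
}

#' @param path File path for the serialized model.
#' @rdname train_pair_classifier
#' @export
save_pair_classifier <- function(model, path) {
  stopifnot(inherits(model, "pair_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @param model A `pair_classifier`.
#' @rdname train_pair_classifier
#' @export
load_pair_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pair_classifier")) {
    stop("file does not contain a pair_classifier: ", path)
  }
  model
}

#' Classify one protein pair with a trained model
#'
#' The positive-class probability is thresholded at 0.5 (majority vote).
#' With the default absolute-difference encoding the decision is symmetric
#' in the two proteins.
#'
#' @param model A [pair_classifier][train_pair_classifier].
#' @param a,b Feature vectors in the model's layout.
#' @return A list with `label` (logical) and `score` (positive-class
#'   probability in \[0, 1\]).
#' @export
predict_pair <- function(model, a, b) {
  stopifnot(inherits(model, "pair_classifier"))
  layout_a <- attr(a, "layout") %||% FEATURE_LAYOUT_VERSION
  if (!identical(model$feature_layout, FEATURE_LAYOUT_VERSION) ||
      !identical(layout_a, model$feature_layout)) {
    stop("feature layout mismatch: model=", model$feature_layout,
         ", featurizer=", FEATURE_LAYOUT_VERSION)
  }
  enc <- matrix(encode_pair(a, b, method = model$encoding), nrow = 1)
  colnames(enc) <- paste0("f", seq_len(ncol(enc)))
  score <- predict(model$forest, data.frame(enc),
                   num.threads = 1)$predictions[1, "positive"]
  list(label = unname(score >= 0.5), score = unname(score))
}

# All-pairs classifier similarity between two feature matrices. In ML mode
# a pair that already passes the Features-mode threshold is accepted without
# consulting the forest; the classifier decides the remaining pairs.
predict_pair_matrix <- function(model, A, B,
                                match_cfg = feature_match_config(),
                                union_features = TRUE) {
  stopifnot(inherits(model, "pair_classifier"))
  base <- if (union_features) {
    match_by_features_matrix(A, B, match_cfg)
  } else {
    matrix(FALSE, nrow(A), nrow(B), dimnames = list(rownames(A), rownames(B)))
  }
  todo <- which(!base, arr.ind = TRUE)
  if (nrow(todo) > 0) {
    enc <- abs(A[todo[, 1], , drop = FALSE] - B[todo[, 2], , drop = FALSE])
    colnames(enc) <- paste0("f", seq_len(ncol(enc)))
    scores <- predict(model$forest, data.frame(enc),
                      num.threads = 1)$predictions[, "positive"]
    base[todo] <- scores >= 0.5
  }
  base
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN). A metric with a zero denominator is returned as
#' `NA` and flagged in `undefined`. Values are exact; rounding (4 decimals)
#' happens only in the print method.
#'
#' @param tn,fn,tp,fp Non-negative confusion-matrix counts.
#' @return An object of class `classification_metrics`.
#' @export
classification_metrics <- function(tn, fn, tp, fp) {
  counts <- c(tn = tn, fn = fn, tp = tp, fp = fp)
  if (any(counts < 0)) stop("counts must be non-negative")
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else {
    undefined <- c(undefined, "f1"); NA_real_
  }
  structure(list(tn = tn, fn = fn, tp = tp, fp = fp,
                 sensitivity = sens, specificity = spec, f1 = f1,
                 undefined = undefined),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 4, ...) {
  cat("TN=", x$tn, " FN=", x$fn, " TP=", x$tp, " FP=", x$fp, "\n",
      "sensitivity=", round(x$sensitivity, digits),
      " specificity=", round(x$specificity, digits),
      " F1=", round(x$f1, digits), "\n", sep = "")
  if (length(x$undefined) > 0) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a pair classifier on a labeled pair table
#'
#' @param model A [pair_classifier][train_pair_classifier].
#' @param pair_table A [build_pair_table()] result.
#' @return A [classification_metrics()] object.
#' @export
evaluate_pair_classifier <- function(model, pair_table) {
  stopifnot(inherits(model, "pair_classifier"),
            inherits(pair_table, "pair_table"))
  x <- data.frame(pair_table$x)
  scores <- predict(model$forest, x, num.threads = 1)$predictions[, "positive"]
  pred <- scores >= 0.5
  truth <- pair_table$y == "positive"
  classification_metrics(tn = sum(!pred & !truth), fn = sum(!pred & truth),
                         tp = sum(pred & truth), fp = sum(pred & !truth))
}
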