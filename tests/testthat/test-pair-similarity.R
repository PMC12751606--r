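# Pair similarity: threshold matching, pair encoding, training-table
# construction, forest training, classification metrics.

test_that("feature matching applies the count-within-tolerance rule", {
  v <- runif(60, 0, 10)
  expect_true(match_by_features(v, v, feature_match_config(60, 1)))
  # exactly 25 coordinates within tolerance -> similar; 24 -> not
  w <- v + 100
  w[1:25] <- v[1:25] + 1
  expect_true(match_by_features(v, w, feature_match_config(25, 1)))
  w[25] <- v[25] + 100
  expect_false(match_by_features(v, w, feature_match_config(25, 1)))
  # symmetry
  expect_equal(match_by_features(v, w), match_by_features(w, v))
  expect_error(match_by_features(v, v[1:59]), "length")
})

test_that("loosening the matching rule never breaks similarity", {
  set.seed(411)
  for (rep in 1:20) {
    a <- runif(60, 0, 5)
    b <- a + rnorm(60)
    for (mm in c(60, 40, 25, 10)) {
      for (tol in c(1, 2)) {
        if (match_by_features(a, b, feature_match_config(mm, tol))) {
          expect_true(match_by_features(a, b, feature_match_config(mm, tol + 1)))
          if (mm > 1) {
            expect_true(match_by_features(a, b,
                                          feature_match_config(mm - 1, tol)))
          }
        }
      }
    }
  }
})

test_that("pair encoding is the symmetric absolute difference", {
  v <- runif(60)
  expect_equal(encode_pair(v, v), rep(0, 60), ignore_attr = TRUE)
  a <- c(1, 3, rep(0, 58)); b <- c(4, 1, rep(0, 58))
  expect_equal(encode_pair(a, b)[1:2], c(3, 2))
  w <- runif(60)
  expect_equal(encode_pair(v, w), encode_pair(w, v))
  expect_error(encode_pair(v, w[1:10]), "length")
  expect_length(encode_pair(v, w, method = "concat"), 120)
})

test_that("pair tables follow the ratio protocol with negatives first", {
  set.seed(412)
  pairs <- data.frame(
    seq_a = replicate(110, random_protein(30)),
    seq_b = replicate(110, random_protein(30)),
    label = rep(c(TRUE, FALSE), c(10, 100)),
    stringsAsFactors = FALSE)
  tab <- build_pair_table(pairs, ratio = 3, seed = 5)
  expect_equal(tab$n_positive, 10)
  expect_equal(tab$n_negative, 30)
  expect_equal(as.character(tab$y),
               rep(c("negative", "positive"), c(30, 10)))
  tab2 <- build_pair_table(pairs, ratio = 3, seed = 5)
  expect_identical(tab$x, tab2$x)
  expect_warning(build_pair_table(pairs, ratio = 50, seed = 5),
                 "only 100 negatives")
  expect_error(build_pair_table(pairs[pairs$label, ], ratio = 3), "negative")
  expect_error(build_pair_table(pairs[!pairs$label, ], ratio = 3), "positive")
  expect_error(build_pair_table(pairs, ratio = 0), "ratio")

  arff <- tempfile(fileext = ".arff")
  write_pair_arff(tab, arff)
  lines <- readLines(arff)
  attrs <- grep("^@attribute", lines, value = TRUE)
  expect_equal(attrs[length(attrs)], "@attribute class {negative,positive}")
  data_rows <- lines[(grep("^@data", lines) + 1):length(lines)]
  expect_equal(grepl("negative$", data_rows),
               rep(c(TRUE, FALSE), c(30, 10)))
})

test_that("forest training is seeded, configured and separable-consistent", {
  set.seed(413)
  # linearly separable: positives have tiny encoded differences
  n <- 40
  x <- rbind(matrix(runif(n * 60, 5, 10), n),   # negatives
             matrix(runif(n * 60, 0, 0.5), n))  # positives
  tab <- structure(list(
    x = `colnames<-`(x, paste0("f", 1:60)),
    y = factor(rep(c("negative", "positive"), each = n),
               levels = c("negative", "positive")),
    n_negative = n, n_positive = n,
    encoding = "absdiff", layout = "gcppi-60-v1"), class = "pair_table")
  m <- train_pair_classifier(tab, forest_config(seed = 9))
  expect_equal(m$forest$num.trees, 500)
  met <- evaluate_pair_classifier(m, tab)
  expect_equal(met$sensitivity, 1.0)
  expect_equal(met$specificity, 1.0)

  # reproducible training and bit-compatible serialization round trip
  m2 <- train_pair_classifier(tab, forest_config(seed = 9))
  p1 <- predict_pair(m, x[1, ] * 0 + 0.2, x[1, ] * 0)
  p2 <- predict_pair(m2, x[1, ] * 0 + 0.2, x[1, ] * 0)
  expect_identical(p1, p2)
  f <- tempfile(fileext = ".rds")
  save_pair_classifier(m, f)
  m3 <- load_pair_classifier(f)
  expect_identical(predict_pair(m3, x[1, ] * 0 + 0.2, x[1, ] * 0), p1)

  single <- tab; single$y <- factor(rep("negative", 2 * n),
                                    levels = c("negative", "positive"))
  expect_error(train_pair_classifier(single), "both classes")
})

test_that("pair prediction is symmetric and layout-guarded", {
  set.seed(414)
  n <- 30
  x <- rbind(matrix(runif(n * 60, 5, 10), n),
             matrix(runif(n * 60, 0, 0.5), n))
  tab <- structure(list(
    x = `colnames<-`(x, paste0("f", 1:60)),
    y = factor(rep(c("negative", "positive"), each = n),
               levels = c("negative", "positive")),
    n_negative = n, n_positive = n,
    encoding = "absdiff", layout = "gcppi-60-v1"), class = "pair_table")
  m <- train_pair_classifier(tab, forest_config(seed = 2))
  a <- runif(60, 0, 3); b <- runif(60, 0, 3)
  expect_identical(predict_pair(m, a, b), predict_pair(m, b, a))
  # a zero-difference pair is positive for a model trained this way
  expect_true(predict_pair(m, a, a)$label)
  stale <- m; stale$feature_layout <- "gcppi-60-v0"
  expect_error(predict_pair(stale, a, b), "layout")
})

test_that("classification metrics reproduce printed confusion-table rows", {
  # independently verified row arithmetic at 4-decimal display rounding
  rows <- list(
    list(c(1713, 14, 26, 35), c(0.6500, 0.9799, 0.5149)),
    list(c(320, 9, 13, 7), c(0.5909, 0.9786, 0.6190)),
    list(c(130, 9, 19, 13), c(0.6786, 0.9091, 0.6333)))
  for (r in rows) {
    m <- classification_metrics(r[[1]][1], r[[1]][2], r[[1]][3], r[[1]][4])
    got <- c(m$sensitivity, m$specificity, m$f1)
    expect_true(all(abs(got - r[[2]]) <= 1e-4 + 1e-12),
                info = paste(r[[1]], collapse = ","))
  }
  d <- classification_metrics(0, 0, 5, 0)
  expect_equal(d$sensitivity, 1.0)
  expect_true(is.na(d$specificity))
  expect_true("specificity" %in% d$undefined)
  expect_error(classification_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("a default-configured forest recovers synthetic similarity", {
  cfg <- simulation_config(n_genomes = 4, genes_per_genome = 60,
                           family_identity = 0.8, seed = 11)
  pairs <- simulate_pair_dataset(cfg, ratio = 3, seed = 2)
  set.seed(5)
  idx <- sample(nrow(pairs))
  cut <- floor(0.7 * nrow(pairs))
  train <- pairs[idx[seq_len(cut)], ]
  test <- pairs[idx[(cut + 1):nrow(pairs)], ]
  tab <- build_pair_table(train, ratio = 3, seed = 1)
  model <- train_pair_classifier(tab, forest_config(seed = 42))
  held <- suppressWarnings(build_pair_table(test, ratio = 1000, seed = 1))
  met <- evaluate_pair_classifier(model, held)
  expect_gte(met$sensitivity, 0.9)
  expect_gte(met$specificity, 0.9)

  # sensitivity on ortholog pairs degrades as families diverge
  sens_at <- vapply(c(0.9, 0.7, 0.5), function(ident) {
    sim <- simulate_proteome_set(simulation_config(
      n_genomes = 3, genes_per_genome = 30, family_identity = ident,
      seed = 77))
    ort <- sim$truth$identities
    seqs <- do.call(rbind, sim$genomes)
    smap <- setNames(seqs$sequence, seqs$id)
    fa <- do.call(rbind, lapply(smap[ort$id_a], function(s)
      suppressWarnings(featurize(s))))
    fb <- do.call(rbind, lapply(smap[ort$id_b], function(s)
      suppressWarnings(featurize(s))))
    enc <- abs(fa - fb)
    colnames(enc) <- paste0("f", 1:60)
    mean(stats::predict(model$forest, data.frame(enc),
                        num.threads = 1)$predictions[, "positive"] >= 0.5)
  }, 0)
  expect_true(all(diff(sens_at) <= 0))
})
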