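# Replicate-agreement statistics and the experiment grid.

test_that("weighted global presence mean follows its frequency weighting", {
  expect_equal(mgp(list(c("a", "b"), c("a", "b"), c("a", "b"))), 100)
  # f = {a: 1, b: .5, c: .5} -> 100 * 1.5 / 2
  expect_equal(mgp(list(c("a", "b"), c("a", "c"))), 75)
  expect_equal(mgp(list(c("a", "b"))), 100)  # single replicate
  expect_error(mgp(list(character(0), character(0))), "empty")
})

test_that("pairwise Jaccard matches direct set arithmetic", {
  same <- pairwise_jaccard(list(c("a", "b"), c("a", "b")))
  expect_equal(same$mean, 1)
  expect_equal(same$matrix, matrix(1, 2, 2))
  expect_equal(pairwise_jaccard(list("a", "b"))$mean, 0)
  expect_equal(pairwise_jaccard(list(c("a", "b", "c"),
                                     c("b", "c", "d")))$mean, 0.5)
  deg <- pairwise_jaccard(list(character(0), character(0)))
  expect_equal(deg$mean, 1)
  expect_true(attr(deg, "degenerate"))
  expect_error(pairwise_jaccard(list("a")), "at least 2")
})

test_that("adapted Fleiss' kappa equals the textbook computation", {
  expect_equal(as.numeric(fleiss_kappa(list(c("a", "b"), c("a", "b"),
                                            c("a", "b")),
                                       universe = letters[1:5])), 1)
  # 3 raters, 4 items, hand-built rating table:
  # item a: 3 selections, b: 2, c: 1, d: 0
  sets <- list(c("a", "b"), c("a", "b", "c"), "a")
  uni <- c("a", "b", "c", "d")
  # independent direct-formula oracle
  sel <- c(3, 2, 1, 0); r <- 3
  nij <- cbind(sel, r - sel)
  p_i <- (rowSums(nij^2) - r) / (r * (r - 1))
  p_j <- colSums(nij) / (4 * r)
  want <- (mean(p_i) - sum(p_j^2)) / (1 - sum(p_j^2))
  expect_equal(as.numeric(fleiss_kappa(sets, uni)), want)
  # every rater selects everything -> expected agreement 1, flagged
  all_sel <- fleiss_kappa(list(uni, uni), universe = uni)
  expect_equal(as.numeric(all_sel), 1)
  expect_true(attr(all_sel, "degenerate"))
  expect_error(fleiss_kappa(list("z", "z"), universe = c("a")), "universe")
})

test_that("Kendall ratio positive counts concordant shared pairs", {
  expect_equal(as.numeric(kendall_ratio_positive(
    list(c("a", "b", "c"), c("a", "b", "c")))), 1)
  expect_equal(as.numeric(kendall_ratio_positive(
    list(c("a", "b", "c"), c("c", "b", "a")))), 0)
  expect_equal(as.numeric(kendall_ratio_positive(
    list(c("a", "b", "c"), c("a", "c", "b")))), 2 / 3)
  skipped <- kendall_ratio_positive(list(c("a", "b"), c("a", "b"),
                                         c("x", "y")))
  expect_equal(attr(skipped, "skipped"), 2)
  expect_error(kendall_ratio_positive(list(c("a", "b"), c("x", "y"))),
               "shares")
})

test_that("multi-sample KS distance is the max pairwise ECDF distance", {
  expect_equal(ks_multi(list(1:5, 1:5)), 0)
  expect_equal(ks_multi(list(c(0, 0, 0), c(1, 1, 1))), 1)
  expect_equal(ks_multi(list(c(1, 2, 3, 4), c(1, 2, 3, 10))), 0.25)
  expect_error(ks_multi(list(1:3, numeric(0))), "empty")
  # cross-check against the stats two-sample statistic
  set.seed(451)
  x <- rnorm(40); y <- rnorm(40, 1)
  want <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
  expect_equal(ks_multi(list(x, y)), want, tolerance = 1e-12)
})

test_that("agreement statistics ignore replicate order and stay in range", {
  set.seed(452)
  sets <- replicate(5, sample(letters, 8), simplify = FALSE)
  perm <- sample(5)
  expect_equal(mgp(sets), mgp(sets[perm]))
  expect_equal(pairwise_jaccard(sets)$mean,
               pairwise_jaccard(sets[perm])$mean)
  expect_equal(as.numeric(fleiss_kappa(sets, letters)),
               as.numeric(fleiss_kappa(sets[perm], letters)))
  expect_equal(as.numeric(kendall_ratio_positive(sets)),
               as.numeric(kendall_ratio_positive(sets[perm])))
  samples <- replicate(4, rnorm(20), simplify = FALSE)
  expect_equal(ks_multi(samples), ks_multi(samples[sample(4)]))
  expect_true(mgp(sets) >= 0 && mgp(sets) <= 100)
  expect_true(pairwise_jaccard(sets)$mean >= 0 &&
              pairwise_jaccard(sets)$mean <= 1)
  expect_lte(as.numeric(fleiss_kappa(sets, letters)), 1)
  kr <- as.numeric(kendall_ratio_positive(sets))
  expect_true(kr >= 0 && kr <= 1)
  expect_true(ks_multi(samples) >= 0 && ks_multi(samples) <= 1)
})

test_that("deterministic replicates reach the perfect-agreement limit", {
  sim <- smoke_simulation()
  nets <- lapply(1:3, function(r)
    infer_ppi_networks(sim$genomes, mode = "features",
                       seed = r)$networks[[1]])
  stats <- stability_statistics(nets, metric = "degree", top_n = 10)
  expect_equal(stats$mgp, 100)
  expect_equal(stats$jaccard_mean, 1)
  expect_equal(stats$fleiss_kappa, 1)
  expect_equal(stats$kendall_rp, 1)
  expect_equal(stats$ks_multi, 0)
})

test_that("the full-scale grid has 180 configurations; a smoke grid runs", {
  expect_equal(nrow(stability_grid()), 180)
  expect_equal(nrow(stability_grid(modes = "ml", n_files = c(10, 20),
                                   top_n = c(10, 100),
                                   metrics = c("degree", "bridging"))), 8)
  # reduced-scale smoke run through the real orchestrator
  smoke <- stability_grid(modes = "ml", n_files = 3, top_n = 20,
                          metrics = "degree")
  out_dir <- file.path(tempdir(), "stab-smoke")
  rep_net <- function(mode, n_files, seed) make_ris_replicate(seed %% 997)
  report <- run_stability_experiment(rep_net, smoke, replicates = 3,
                                     seed = 5, out_dir = out_dir)
  expect_s3_class(report, "stability_report")
  expect_equal(report$status, "ok")
  expect_true(all(c("mgp", "jaccard_mean", "fleiss_kappa", "kendall_rp",
                    "ks_multi") %in% names(report)))
  expect_true(file.exists(file.path(out_dir, "stability_report.csv")))
  expect_length(list.files(out_dir, pattern = "^top_.*rep0[1-3]\\.csv$"), 3)
  # a failing pipeline flags its configuration but does not abort
  bad <- run_stability_experiment(function(...) stop("boom"), smoke,
                                  replicates = 2, seed = 1)
  expect_match(bad$status, "failed")
})
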