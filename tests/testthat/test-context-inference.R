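# Phylogenetic-profile and gene-neighborhood interaction inference.

three_genome_toy <- function() {
  # family f1 in genomes 1+2, f2 everywhere, f3 only genome 1
  g1 <- make_proteome(c("a1", "b1", "c1"), rep("ACDEF", 3), "G1")
  g2 <- make_proteome(c("a2", "b2"), rep("ACDEF", 2), "G2")
  g3 <- make_proteome("b3", "ACDEF", "G3")
  sim <- pairs_predicate(data.frame(
    a = c("a1", "b1", "b1", "b2"),
    b = c("a2", "b2", "b3", "b3"), stringsAsFactors = FALSE))
  list(genomes = list(g1, g2, g3), sim = sim)
}

test_that("presence profiles reflect cross-genome similarity", {
  toy <- three_genome_toy()
  pp <- build_presence_profiles(toy$genomes, toy$sim)
  p1 <- pp$presence[[1]]
  expect_true(all(p1[, "G1"]))                     # own genome always true
  expect_equal(unname(p1["a1", ]), c(TRUE, TRUE, FALSE))   # family in {1,2}
  expect_equal(unname(p1["b1", ]), c(TRUE, TRUE, TRUE))    # everywhere
  expect_equal(unname(p1["c1", ]), c(TRUE, FALSE, FALSE))  # own only
  expect_equal(pp$profiles[[1]]$key, c("110", "111", "100"))
  expect_error(build_presence_profiles(toy$genomes[1], toy$sim),
               "at least 2")
})

test_that("identical proteomes give all-true profiles and complete graphs", {
  ids <- c("x", "y", "z")
  gs <- lapply(1:3, function(g)
    make_proteome(paste0(ids, g), rep("MKV", 3), paste0("G", g)))
  all_sim <- function(pi, pj) {
    m <- matrix(TRUE, nrow(pi), nrow(pj), dimnames = list(pi$id, pj$id))
    m
  }
  pp <- build_presence_profiles(gs, all_sim)
  expect_true(all(pp$presence[[2]]))
  edges <- profile_interactions(pp, genome = 1)
  expect_equal(nrow(edges), 3)  # complete triangle
  expect_equal(unique(edges$evidence), "profile")
})

test_that("profile difference tolerance has Hamming semantics", {
  prof <- data.frame(id = c("p", "q"), key = c("110", "111"),
                     group_size = c(1, 1), stringsAsFactors = FALSE)
  expect_equal(nrow(profile_interactions(prof, cfg = profile_config(0))), 0)
  e1 <- profile_interactions(prof, cfg = profile_config(1))
  expect_equal(nrow(e1), 1)
  # a protein present only in its own genome generates no edges
  lone <- data.frame(id = c("p", "q"), key = c("100", "100"),
                     group_size = c(2, 2), stringsAsFactors = FALSE)
  expect_equal(nrow(profile_interactions(lone, cfg = profile_config(3))), 0)
})

test_that("profile edge sets grow monotonically with tolerance", {
  set.seed(421)
  keys <- replicate(30, paste(c("1", sample(c("0", "1"), 4, replace = TRUE)),
                              collapse = ""))
  prof <- data.frame(id = sprintf("p%02d", 1:30), key = keys,
                     group_size = 1, stringsAsFactors = FALSE)
  prev <- character(0)
  for (tol in 0:3) {
    e <- profile_interactions(prof,
                              cfg = profile_config(tol, ris_trigger = 1000))
    keys_e <- paste(e$a, e$b)
    expect_true(all(prev %in% keys_e), info = paste("tol", tol))
    prev <- keys_e
  }
})

test_that("oversized identical-profile groups are sampled, not completed", {
  prof <- data.frame(id = sprintf("p%03d", 1:150),
                     key = "111", group_size = 150, stringsAsFactors = FALSE)
  e <- profile_interactions(prof, cfg = profile_config(ris_trigger = 100),
                            seed = 3)
  expect_lt(nrow(e), choose(150, 2))
  expect_gt(nrow(e), 0)
  full <- profile_interactions(prof,
                               cfg = profile_config(ris_trigger = 1000))
  expect_equal(nrow(full), choose(150, 2))  # complete graph x(x-1)/2
  expect_true(all(paste(e$a, e$b) %in% paste(full$a, full$b)))
  # with complete = FALSE the oversized group is filtered out entirely
  none <- profile_interactions(prof, cfg = profile_config(
    complete = FALSE, ris_trigger = 100))
  expect_equal(nrow(none), 0)
})

test_that("edge-estimate diagnostic never exceeds the complete-graph count", {
  for (x in 2:20) {
    expect_lte(profile_edge_estimate(x), x * (x - 1) / 2)
  }
  expect_equal(profile_edge_estimate(3), 1)
  expect_error(profile_edge_estimate(1), ">= 2")
})

test_that("conserved neighborhoods follow the window/quota rule", {
  n <- 10
  g1 <- make_proteome(sprintf("a%02d", 1:n), rep("M", n), "G1")
  g2 <- make_proteome(sprintf("b%02d", 1:n), rep("M", n), "G2")
  sim <- pairs_predicate(data.frame(a = sprintf("a%02d", 1:n),
                                    b = sprintf("b%02d", 1:n)))
  cfg <- neighborhood_config(w1 = 10, cw1 = 4)
  got <- neighborhood_interactions(list(g1, g2), sim, cfg, target = 1)
  # independent enumeration of the stated rule on this fully conserved toy
  exp_a <- character(0); exp_b <- character(0)
  win <- function(i) max(1, i - 4):min(n, i + 5)
  for (i in 1:n) {
    w_t <- win(i); w_o <- win(i)       # anchor at same index, same order
    hit <- intersect(w_t, w_o)
    if (length(hit) >= 4) {
      for (w in setdiff(hit, i)) {
        exp_a <- c(exp_a, sprintf("a%02d", i))
        exp_b <- c(exp_b, sprintf("a%02d", w))
      }
    }
  }
  want <- unique_undirected(data.frame(a = exp_a, b = exp_b))
  expect_setequal(paste(got$a, got$b), paste(want$a, want$b))
  expect_equal(unique(got$evidence), "neighborhood")
  # every windowed gene is linked to its conserved window partners
  expect_true(all(sprintf("a%02d", 1:n) %in% unique(c(got$a, got$b))))
})

test_that("neighborhood evidence needs the conservation quota", {
  # no similarity at all -> empty
  g1 <- make_proteome(sprintf("a%d", 1:6), rep("M", 6), "G1")
  g2 <- make_proteome(sprintf("b%d", 1:6), rep("M", 6), "G2")
  none <- pairs_predicate(data.frame(a = character(0), b = character(0)))
  expect_equal(nrow(neighborhood_interactions(list(g1, g2), none,
                                              target = 1)), 0)
  # only 3 conserved genes in any window with cw1 = 4 -> empty
  three <- pairs_predicate(data.frame(a = c("a1", "a2", "a3"),
                                      b = c("b1", "b2", "b3")))
  expect_equal(nrow(neighborhood_interactions(
    list(g1, g2), three, neighborhood_config(w1 = 10, cw1 = 4),
    target = 1)), 0)
  # the same pattern passes with cw1 = 3
  expect_gt(nrow(neighborhood_interactions(
    list(g1, g2), three, neighborhood_config(w1 = 10, cw1 = 3),
    target = 1)), 0)
  expect_error(neighborhood_config(w1 = 3, cw1 = 4), "exceed")
})

test_that("dynamic expansion stops when the quota fails", {
  n <- 12
  g1 <- make_proteome(sprintf("a%02d", 1:n), rep("M", n), "G1")
  g2 <- make_proteome(sprintf("b%02d", 1:n), rep("M", n), "G2")
  # only the first 4 genes are conserved
  sim <- pairs_predicate(data.frame(a = sprintf("a%02d", 1:4),
                                    b = sprintf("b%02d", 1:4)))
  dyn <- neighborhood_interactions(
    list(g1, g2), sim,
    neighborhood_config(w1 = 10, cw1 = 3, expansion = "dynamic",
                        dynamic_start = 3), target = 1)
  fix <- neighborhood_interactions(
    list(g1, g2), sim, neighborhood_config(w1 = 10, cw1 = 3), target = 1)
  expect_true(all(paste(dyn$a, dyn$b) %in% paste(fix$a, fix$b)))
})

test_that("network assembly dedupes, unions evidence and guards endpoints", {
  e1 <- data.frame(a = "A", b = "B", evidence = "profile")
  e2 <- data.frame(a = "B", b = "A", evidence = "neighborhood")
  net <- assemble_network(list(e1, e2), c("A", "B", "C"), genome_id = "G")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$evidence, "neighborhood,profile")
  expect_equal(net$nodes, c("A", "B"))  # isolated C excluded by default
  withiso <- assemble_network(list(e1), c("A", "B", "C"),
                              include_isolated = TRUE)
  expect_equal(withiso$nodes, c("A", "B", "C"))
  empty <- assemble_network(list(), c("A", "B"))
  expect_equal(nrow(empty$edges), 0)
  expect_error(assemble_network(list(data.frame(a = "A", b = "Z",
                                                evidence = "profile")),
                                c("A", "B")), "Z")
  # 5-protein toy, hand enumeration
  es <- list(data.frame(a = c("p1", "p2"), b = c("p2", "p3"),
                        evidence = "profile"),
             data.frame(a = "p3", b = "p2", evidence = "neighborhood"),
             data.frame(a = "p4", b = "p5", evidence = "profile"))
  net5 <- assemble_network(es, paste0("p", 1:5))
  expect_equal(length(net5$nodes), 5)
  expect_equal(nrow(net5$edges), 3)
})
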