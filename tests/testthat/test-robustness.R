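test_that("a degenerate block of identical trees equals the single fit", {
  toy <- make_toy(n = 20, seed = 41, slope = 0.6)
  spec <- model_spec("y", "x1", family = "gaussian")
  single <- fit_pgls(toy$data, spec, toy$tree)
  blk <- list(toy$tree, toy$tree, toy$tree)
  summ <- fit_over_treeblock(toy$data, spec, blk)
  focal <- summ[summ$term == "x1", ]
  expect_equal(focal$median_beta, unname(single$coefficients["x1"]),
               tolerance = 1e-10)
  expect_equal(focal$ci95_low, focal$ci95_high, tolerance = 1e-12)
  expect_equal(focal$median_stat, unname(single$t["x1"]),
               tolerance = 1e-10)
})

test_that("two-tree blocks interpolate the median linearly", {
  toy <- make_toy(n = 20, seed = 42, slope = 0.6)
  spec <- model_spec("y", "x1", family = "gaussian")
  b1 <- simulate_treeblock(toy$tree, n_trees = 1, jitter = 0.4, seed = 1)
  b2 <- simulate_treeblock(toy$tree, n_trees = 1, jitter = 0.4, seed = 2)
  f1 <- fit_pgls(toy$data, spec, b1[[1]])$coefficients["x1"]
  f2 <- fit_pgls(toy$data, spec, b2[[1]])$coefficients["x1"]
  summ <- fit_over_treeblock(toy$data, spec, c(b1, b2))
  expect_equal(summ[summ$term == "x1", "median_beta"],
               unname((f1 + f2) / 2), tolerance = 1e-10)
})

test_that("tree-block summaries are invariant to tree order", {
  toy <- make_toy(n = 18, seed = 43)
  spec <- model_spec("y", "x1", family = "gaussian")
  blk <- simulate_treeblock(toy$tree, n_trees = 9, jitter = 0.3, seed = 3)
  s1 <- fit_over_treeblock(toy$data, spec, blk)
  s2 <- fit_over_treeblock(toy$data, spec, rev(blk))
  expect_equal(s1$median_beta, s2$median_beta, tolerance = 1e-12)
  expect_equal(s1$ci95_low, s2$ci95_low, tolerance = 1e-12)
})

test_that("median slope and median statistic share a sign when all fits do", {
  toy <- make_toy(n = 40, seed = 44, slope = 1.2)
  spec <- model_spec("y", "x1", family = "gaussian")
  blk <- simulate_treeblock(toy$tree, n_trees = 11, jitter = 0.2, seed = 4)
  summ <- fit_over_treeblock(toy$data, spec, blk)
  B <- attr(summ, "per_tree_beta")[, "x1"]
  if (all(B > 0) || all(B < 0)) {
    focal <- summ[summ$term == "x1", ]
    expect_equal(sign(focal$median_beta), sign(focal$median_stat))
  }
})

test_that("a planted 10-SD outlier is flagged influential", {
  toy <- make_toy(n = 30, seed = 45, slope = 0.5)
  d <- plant_outlier(toy$data, toy$data$species[7], 10)
  spec <- model_spec("y", "x1", family = "gaussian")
  rep <- leave_one_out_influence(d, spec, toy$tree)
  expect_true(rep$influential[rep$species == toy$data$species[7]])
})

test_that("zero-spread leave-one-out estimates give all-zero sdiff", {
  tr <- simulate_tree(n_species = 12, tree_model = "star", seed = 46)
  d <- data.frame(species = tr$tip.label,
                  x1 = rep(c(-1, 1), 6), y = rep(c(0, 1), 6))
  spec <- model_spec("y", "x1", family = "gaussian")
  rep <- leave_one_out_influence(d, spec, tr)
  # every deletion leaves the same exact-fit slope: spread is zero
  expect_true(all(rep$sdiff == 0))
  expect_false(any(rep$influential))
})

test_that("influence reports are permutation-equivariant in species order", {
  toy <- make_toy(n = 16, seed = 47)
  spec <- model_spec("y", "x1", family = "gaussian")
  r1 <- leave_one_out_influence(toy$data, spec, toy$tree)
  set.seed(5)
  perm <- sample(nrow(toy$data))
  r2 <- leave_one_out_influence(toy$data[perm, ], spec, toy$tree)
  m <- match(r1$species, r2$species)
  expect_equal(r2$sdiff[m], r1$sdiff, tolerance = 1e-9)
  expect_equal(r2$influential[m], r1$influential)
})
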