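test_that("tree simulation is deterministic and ultrametric", {
  t1 <- simulate_tree(n_species = 30, seed = 71)
  t2 <- simulate_tree(n_species = 30, seed = 71)
  expect_identical(write_newick(t1), write_newick(t2))
  depths <- diag(phylo_covariance(t1))
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(unname(max(depths)), 1, tolerance = 1e-9)
  star <- simulate_tree(n_species = 10, tree_model = "star", seed = 72)
  C <- phylo_covariance(star)
  expect_equal(unname(C), diag(diag(C)))
})

test_that("zero jitter copies the base tree; jitter is mean-corrected", {
  base <- simulate_tree(n_species = 12, seed = 73)
  blk0 <- simulate_treeblock(base, n_trees = 3, jitter = 0, seed = 1)
  for (t in blk0) expect_identical(write_newick(t), write_newick(base))
  blk <- simulate_treeblock(base, n_trees = 400, jitter = 0.3, seed = 2)
  mean_len <- mean(vapply(blk, function(t) mean(t$edge.length), numeric(1)))
  expect_lt(abs(mean_len / mean(base$edge.length) - 1), 0.05)
  for (t in blk) expect_setequal(t$tip.label, base$tip.label)
})

test_that("trait generation is a pure function of config and seed", {
  tree <- simulate_tree(n_species = 20, seed = 74)
  cfg <- sim_config(n_species = 20, slopes = c(x1 = 0.5), seed = 75)
  d1 <- simulate_traits(tree, cfg)
  d2 <- simulate_traits(tree, cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$prevalence >= 0 & d1$prevalence <= 1))
  expect_true(all(d1$n_surveyed >= 5 & d1$n_surveyed <= 50))
})

test_that("single-individual surveys give prevalence in {0, 1}", {
  tree <- simulate_tree(n_species = 15, seed = 76)
  cfg <- sim_config(n_species = 15, slopes = c(x1 = 0),
                    n_individuals = c(1, 1), seed = 77)
  d <- simulate_traits(tree, cfg)
  expect_true(all(d$prevalence %in% c(0, 1)))
})

test_that("Brownian traits reproduce the tree covariance across replicates", {
  tree <- simulate_tree(n_species = 20, seed = 78)
  C <- phylo_covariance(tree)
  set.seed(79)
  k <- 1000
  Z <- ppcm:::.rbm(C, k)
  S <- tcrossprod(Z) / k
  rel_err <- norm(S - C, "F") / norm(C, "F")
  ## Wishart mean: E||S - C||_F^2 = (tr(C^2) + tr(C)^2) / k; the observed
  ## error must sit near that Monte-Carlo floor (~0.086 here)
  expected <- sqrt((sum(C^2) + sum(diag(C))^2) / k) / norm(C, "F")
  expect_lt(rel_err, 1.5 * expected)
  expect_lt(expected, 0.1)
})

test_that("planted outliers are recorded and zero displacement is identity", {
  toy <- make_toy(n = 10, seed = 80)
  d0 <- plant_outlier(toy$data, toy$data$species[3], 0)
  expect_equal(d0$y, toy$data$y)
  d1 <- plant_outlier(toy$data, toy$data$species[3], 10)
  expect_equal(attr(d1, "outlier")$species, toy$data$species[3])
  expect_gt(abs(d1$y[3] - toy$data$y[3]), 5)
  expect_error(plant_outlier(toy$data, "nope", 2), "unknown species")
})

test_that("study-shaped datasets pass validation and carry planted effects", {
  cfg <- sim_config(n_species = 40, n_trees_block = 5, seed = 81)
  study <- simulate_study(cfg, effects = list(
    prevalence_fdb = c(pct_diet_handling = 1)))
  d <- study$data
  expect_true(all(c("pct_diet_search", "pct_diet_handling",
                    "brain_volume_ml", "hatch_rate", "n_surveyed") %in%
                    names(d)))
  expect_true(all(d$pct_diet_search >= d$pct_diet_handling))
  expect_true(all(d$prevalence_fdb >= 0 & d$prevalence_fdb <= 1))
  expect_length(study$block, 5L)
  # planted positive association should be visible in the raw correlation
  expect_gt(cor(d$pct_diet_handling, d$prevalence_fdb), 0)
})
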