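test_that("star-tree fit equals Firth-penalized ordinary logistic", {
  star <- simulate_tree(n_species = 40, tree_model = "star", seed = 21)
  cfg <- sim_config(n_species = 40, slopes = c(x1 = 0.8), latent_sd = 0,
                    n_individuals = c(1, 1), seed = 22)
  d <- simulate_traits(star, cfg)
  d$ybin <- as.integer(d$affected > 0)
  f <- fit_phylo_logistic(d, model_spec("ybin", "x1", family = "binomial"),
                          star)
  beta_oracle <- oracle_firth_logistic(d$ybin, rep(1, 40),
                                       cbind(1, d$x1))
  expect_equal(unname(f$coefficients), beta_oracle, tolerance = 1e-4)
  expect_equal(f$g_hat, 0)
})

test_that("binomial counts with trials reproduce the expanded 0/1 fit", {
  star <- simulate_tree(n_species = 25, tree_model = "star", seed = 23)
  cfg <- sim_config(n_species = 25, slopes = c(x1 = 0.5), latent_sd = 0,
                    n_individuals = c(4, 12), seed = 24)
  d <- simulate_traits(star, cfg)
  f <- fit_phylo_logistic(d, model_spec("affected", "x1",
                                        family = "binomial",
                                        trials_column = "n_surveyed"),
                          star)
  beta_oracle <- oracle_firth_logistic(d$affected, d$n_surveyed,
                                       cbind(1, d$x1))
  expect_equal(unname(f$coefficients), beta_oracle, tolerance = 1e-4)
})

test_that("degenerate outcomes raise defined errors", {
  toy <- make_toy(n = 15, seed = 25)
  d <- toy$data
  d$allz <- 0L
  expect_error(fit_phylo_logistic(d, model_spec("allz", "x1",
                                                family = "binomial"),
                                  toy$tree), "all zeros")
  d$allo <- 1L
  expect_error(fit_phylo_logistic(d, model_spec("allo", "x1",
                                                family = "binomial"),
                                  toy$tree), "all ones")
})

test_that("complete separation names the separating predictor", {
  toy <- make_toy(n = 20, seed = 26)
  d <- toy$data
  d$sep <- seq_len(20)
  d$ybin <- as.integer(d$sep > 10)
  expect_error(fit_phylo_logistic(d, model_spec("ybin", "sep",
                                                family = "binomial"),
                                  toy$tree), "sep")
})

test_that("alpha decreases (g rises) when latent phylogenetic signal is strong", {
  set.seed(27)
  g_strong <- numeric(8)
  g_none <- numeric(8)
  for (s in 1:8) {
    tree <- simulate_tree(n_species = 80, seed = 400 + s)
    cfg_s <- sim_config(n_species = 80, slopes = c(x1 = 0), latent_sd = 2,
                        n_individuals = c(20, 40), seed = 500 + s)
    cfg_0 <- sim_config(n_species = 80, slopes = c(x1 = 0), latent_sd = 0,
                        n_individuals = c(20, 40), seed = 600 + s)
    spec <- model_spec("affected", "x1", family = "binomial",
                       trials_column = "n_surveyed")
    g_strong[s] <- fit_phylo_logistic(simulate_traits(tree, cfg_s),
                                      spec, tree)$g_hat
    g_none[s] <- fit_phylo_logistic(simulate_traits(tree, cfg_0),
                                    spec, tree)$g_hat
  }
  expect_gt(mean(g_strong), mean(g_none))
  expect_gt(mean(g_strong), 0.3)
})
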