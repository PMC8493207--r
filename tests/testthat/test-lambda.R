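test_that("profile at lambda = 1 equals the untransformed likelihood", {
  toy <- make_toy(n = 15, seed = 12)
  mfy <- toy$data$y
  X <- cbind(1, toy$data$x1)
  C <- phylo_covariance(toy$tree, toy$data$species)
  expect_equal(pgls_profile_loglik(mfy, X, C, 1), gls_fit(mfy, X, C)$loglik,
               tolerance = 1e-8)
})

test_that("profile is flat on a star tree and the fit equals OLS", {
  star <- simulate_tree(n_species = 15, tree_model = "star", seed = 13)
  cfg <- sim_config(n_species = 15, slopes = c(x1 = 0.4), seed = 14)
  d <- simulate_traits(star, cfg)
  X <- cbind(1, d$x1)
  C <- phylo_covariance(star, d$species)
  lls <- pgls_profile_loglik(d$y, X, C, c(0, 0.3, 0.7, 1))
  expect_lt(max(lls) - min(lls), 1e-8)
  f <- fit_pgls(d, model_spec("y", "x1", family = "gaussian"), star)
  expect_true(f$lambda_unidentifiable)
  ols <- lm(y ~ x1, data = d)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-8)
})

test_that("optimizer matches a fine grid search of the profile", {
  toy <- make_toy(n = 40, seed = 15, lambda = 0.6)
  X <- cbind(1, toy$data$x1)
  C <- phylo_covariance(toy$tree, toy$data$species)
  grid <- seq(0, 1, by = 0.002)
  lls <- pgls_profile_loglik(toy$data$y, X, C, grid)
  lam_grid <- grid[which.max(lls)]
  f <- fit_pgls(toy$data, model_spec("y", "x1", family = "gaussian"),
                toy$tree)
  expect_lt(abs(f$lambda_hat - lam_grid), 0.002 + 1e-8)
})

test_that("forcing lambda = 0 reproduces OLS on the same data", {
  toy <- make_toy(n = 20, seed = 16)
  f <- fit_pgls(toy$data, model_spec("y", "x1", family = "gaussian"),
                toy$tree, lambda = 0)
  ols <- lm(y ~ x1, data = toy$data)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
})

test_that("lambda-ML fit agrees with nlme::gls + corPagel cross-check", {
  skip_if_not_installed("nlme")
  toy <- make_toy(n = 60, seed = 17, slope = 0.5, lambda = 1)
  f <- fit_pgls(toy$data, model_spec("y", "x1", family = "gaussian"),
                toy$tree)
  d <- toy$data
  rownames(d) <- d$species
  ## same lambda, independently coded GLS: coefficients must agree tightly
  ref_fixed <- nlme::gls(y ~ x1, data = d, method = "ML",
                         correlation = ape::corPagel(f$lambda_hat, toy$tree,
                                                     form = ~species,
                                                     fixed = TRUE))
  expect_equal(unname(f$coefficients), unname(coef(ref_fixed)),
               tolerance = 1e-6)
  ## nlme's own ML lambda should land near ours
  ref_ml <- nlme::gls(y ~ x1, data = d, method = "ML",
                      correlation = ape::corPagel(0.8, toy$tree,
                                                  form = ~species))
  lam_ref <- as.numeric(coef(ref_ml$modelStruct$corStruct,
                             unconstrained = FALSE))
  expect_equal(f$lambda_hat, lam_ref, tolerance = 0.05)
})

test_that("phylogenetically permuted outcomes drive lambda toward zero", {
  hits <- 0
  for (s in 1:10) {
    toy <- make_toy(n = 60, seed = 300 + s, slope = 0, lambda = 1)
    d <- toy$data
    set.seed(1000 + s)
    d$y <- sample(d$y)          # destroy the phylogenetic signal
    f <- fit_pgls(d, model_spec("y", "x1", family = "gaussian"), toy$tree)
    if (f$lambda_hat < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 6)
})
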