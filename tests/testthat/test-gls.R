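test_that("gls_fit with identity covariance equals ordinary least squares", {
  set.seed(1)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- 1 + 0.5 * X[, 2] + rnorm(n)
  g <- gls_fit(y, X, diag(n))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(g$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-10)
})

test_that("an exactly linear response gives zero residual variance", {
  tr <- simulate_tree(n_species = 10, seed = 4)
  C <- phylo_covariance(tr)
  set.seed(2)
  x <- rnorm(10)
  y <- 2 + 3 * x
  g <- gls_fit(y, cbind(1, x), C)
  expect_equal(g$sigma2_hat, 0, tolerance = 1e-20)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(g$beta), c(2, 3), tolerance = 1e-10)
})

test_that("Cholesky path matches the dense-inversion oracle on small trees", {
  for (s in 1:4) {
    tr <- simulate_tree(n_species = 4 + s %% 3, seed = 50 + s)
    C <- phylo_covariance(tr)
    n <- nrow(C)
    set.seed(s)
    X <- cbind(1, rnorm(n))
    y <- 0.3 + 0.8 * X[, 2] + rnorm(n)
    g <- gls_fit(y, X, C)
    o <- oracle_gls(y, X, C)
    expect_equal(unname(g$beta), o$beta, tolerance = 1e-10)
    expect_equal(unname(g$se), o$se, tolerance = 1e-10)
    expect_equal(unname(g$t), unname(o$t), tolerance = 1e-10)
  }
})

test_that("scaling y scales beta but leaves t, p and lambda unchanged", {
  toy <- make_toy(n = 25, seed = 8)
  spec <- model_spec("y", "x1", family = "gaussian")
  f1 <- fit_pgls(toy$data, spec, toy$tree)
  d2 <- toy$data
  d2$y <- d2$y * 7
  f2 <- fit_pgls(d2, spec, toy$tree)
  expect_equal(unname(f2$coefficients), unname(f1$coefficients) * 7,
               tolerance = 1e-6)
  expect_equal(f2$t, f1$t, tolerance = 1e-5)
  expect_equal(f2$p, f1$p, tolerance = 1e-5)
  expect_equal(f2$lambda_hat, f1$lambda_hat, tolerance = 1e-4)
})

test_that("scaling V leaves beta, se and t unchanged (sigma2 absorbs it)", {
  tr <- simulate_tree(n_species = 12, seed = 9)
  C <- phylo_covariance(tr)
  set.seed(3)
  X <- cbind(1, rnorm(12))
  y <- rnorm(12)
  g1 <- gls_fit(y, X, C)
  g2 <- gls_fit(y, X, 13 * C)
  expect_equal(g1$beta, g2$beta, tolerance = 1e-12)
  expect_equal(g1$se, g2$se, tolerance = 1e-12)
  expect_equal(g1$t, g2$t, tolerance = 1e-12)
  expect_equal(g2$sigma2_hat, g1$sigma2_hat / 13, tolerance = 1e-12)
})

test_that("singular V and rank-deficient X raise informative errors", {
  n <- 8
  set.seed(4)
  X <- cbind("(Intercept)" = 1, a = rnorm(n))
  y <- rnorm(n)
  expect_error(gls_fit(y, X, matrix(1, n, n)), "singular")
  X2 <- cbind(X, a_copy = X[, "a"])
  expect_error(gls_fit(y, X2, diag(n)), "a_copy")
})
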