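# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths: dense matrix inversion instead of
# Cholesky solves, direct likelihood maximization instead of IRLS.

# GLS by explicit dense inversion: beta = (X'V^-1X)^-1 X'V^-1 y.
oracle_gls <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  G <- solve(XtViX)
  beta <- as.numeric(G %*% t(X) %*% Vi %*% y)
  n <- length(y); p <- ncol(X)
  r <- y - X %*% beta
  sigma2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
  se <- sqrt(sigma2 * diag(G))
  list(beta = beta, se = se, t = beta / se, sigma2 = sigma2)
}

# Firth-penalized logistic regression by direct maximization of the
# penalized log-likelihood l(b) + 0.5*log det I(b).
oracle_firth_logistic <- function(y, m, X) {
  pen_ll <- function(b) {
    eta <- as.numeric(X %*% b)
    mu <- plogis(eta)
    ll <- sum(y * eta - m * log1p(exp(eta)))
    W <- m * mu * (1 - mu)
    ll + 0.5 * determinant(t(X) %*% (W * X), logarithm = TRUE)$modulus
  }
  fit <- optim(rep(0, ncol(X)), function(b) -pen_ll(b), method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Squared partial correlation of y and x given Z, by residualization.
oracle_sq_partial_cor <- function(y, x, Z) {
  ry <- resid(lm(y ~ Z))
  rx <- resid(lm(x ~ Z))
  cor(ry, rx)^2
}

# Small fixed comparative dataset on a known tree, for plumbing tests.
make_toy <- function(n = 20, seed = 42, slope = 0.5, lambda = 1) {
  tree <- simulate_tree(n_species = n, seed = seed)
  cfg <- sim_config(n_species = n, slopes = c(x1 = slope),
                    lambda_true = lambda, seed = seed + 1)
  data <- simulate_traits(tree, cfg)
  list(tree = tree, data = data, cfg = cfg)
}
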