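#' Generalized least squares under a fixed covariance
#'
#' Solves the GLS normal equations through a Cholesky factorization of `V`
#' (the covariance is never inverted explicitly). With `V = I` this reduces
#' to ordinary least squares.
#'
#' The residual variance `sigma2_hat` uses the unbiased divisor `n - p`;
#' the reported log-likelihood is the maximized multivariate-normal
#' log-likelihood (ML divisor `n`).
#'
#' @param y numeric response vector.
#' @param X design matrix (include the intercept column explicitly).
#' @param V symmetric positive-definite covariance matrix, rows aligned
#'   with `y` and `X`.
#' @return list with `beta`, `se`, `t`, `p` (two-sided, `n - p` df),
#'   `sigma2_hat`, `loglik`, `rss`, `r_squared`, `n`, `df_resid`,
#'   `fitted`, `residuals`, and `XtVinvX_inv`.
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimensions of y, X and V do not agree")
  if (n <= p) stop("need n > p; got n = ", n, ", p = ", p)
  L <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix V is singular or not positive definite",
         call. = FALSE))
  ## whiten: V = L'L (upper L), solve L' a = x
  Xw <- forwardsolve(t(L), X)
  yw <- forwardsolve(t(L), y)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, yw)
  resw <- yw - Xw %*% beta
  rss <- sum(resw^2)
  df_resid <- n - p
  sigma2_hat <- rss / df_resid
  R <- qr.R(qrX)
  XtVinvX_inv <- chol2inv(R)
  dimnames(XtVinvX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(sigma2_hat * diag(XtVinvX_inv))
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * stats::pt(-abs(tval), df_resid)
  logdetV <- 2 * sum(log(diag(L)))
  s2ml <- rss / n
  loglik <- if (s2ml > 0)
    -0.5 * (n * log(2 * pi * s2ml) + logdetV + n) else Inf
  ## GLS R^2 against the whitened intercept-only model
  ybar <- sum(yw * forwardsolve(t(L), rep(1, n))) /
    sum(forwardsolve(t(L), rep(1, n))^2)
  tss <- sum((yw - ybar * forwardsolve(t(L), rep(1, n)))^2)
  r_squared <- if (tss > 0) 1 - rss / tss else NA_real_
  fitted <- as.numeric(X %*% beta)
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(as.numeric(se), colnames(X)),
       t = stats::setNames(as.numeric(tval), colnames(X)),
       p = stats::setNames(as.numeric(pval), colnames(X)),
       sigma2_hat = sigma2_hat, loglik = loglik, rss = rss,
       r_squared = r_squared, n = n, df_resid = df_resid,
       fitted = fitted, residuals = y - fitted,
       XtVinvX_inv = XtVinvX_inv)
}

## Closure evaluating the lambda profile log-likelihood cheaply. With
## D = diag(C) and Ct = D^-1/2 C D^-1/2 = U diag(w) U', the transformed
## covariance factors as V(lam) = D^1/2 U diag(lam*w + 1-lam) U' D^1/2
## for every tree, so one eigendecomposition serves all lambda values and
## each evaluation is a weighted least squares.
.profile_closure <- function(y, X, C) {
  n <- length(y)
  p <- ncol(X)
  d <- diag(C)
  if (any(d <= 0))
    stop("covariance has zero root-to-tip distance; lambda profile undefined")
  sdi <- 1 / sqrt(d)
  Ct <- sdi * t(sdi * t(C))      # correlation-like scaling of C
  eg <- eigen(Ct, symmetric = TRUE)
  yt <- crossprod(eg$vectors, sdi * y)
  Xt <- crossprod(eg$vectors, sdi * X)
  ev <- eg$values
  logdet_d <- sum(log(d))
  function(lam) {
    w <- lam * ev + (1 - lam)
    if (any(w <= 1e-12)) return(-Inf)
    sw <- 1 / sqrt(w)
    qrX <- qr(Xt * sw)
    if (qrX$rank < p) return(-Inf)
    resw <- (yt * sw) - qr.fitted(qrX, yt * sw)
    rss <- sum(resw^2)
    if (rss <= 0) return(Inf)
    -0.5 * (n * log(2 * pi * rss / n) + sum(log(w)) + logdet_d + n)
  }
}

#' Profile log-likelihood of Pagel's lambda
#'
#' Evaluates the PGLS log-likelihood at a given `lam`, with the regression
#' coefficients and residual rate profiled out analytically. This is the
#' curve maximized by [fit_pgls()].
#'
#' @param y response vector.
#' @param X design matrix.
#' @param C phylogenetic covariance matrix aligned with `y`.
#' @param lam lambda value(s) in `[0, 1]`; vectorized.
#' @return numeric vector of profile log-likelihoods.
#' @export
pgls_profile_loglik <- function(y, X, C, lam) {
  for (l in lam) {
    if (l < 0 || l > 1) stop("lambda must lie in [0, 1]")
  }
  f <- .profile_closure(y, as.matrix(X), C)
  vapply(lam, f, numeric(1))
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Fits a gaussian comparative regression where the residual covariance is
#' the lambda-transformed Brownian expectation from the tree. Lambda is
#' estimated by maximum likelihood on `[0, 1]` through bounded 1-D
#' optimization from multiple starts (0.1, 0.5, 0.9), with the interval
#' ends also evaluated; likelihood ties are broken toward the smaller
#' lambda. Species with missing values in any model column are dropped
#' (listwise deletion) and the tree is pruned to the remainder before the
#' covariance is built. Standard errors and p-values condition on the
#' estimated lambda (two-sided t, `n - p` df).
#'
#' On a star phylogeny lambda has no effect on the likelihood; the fit is
#' then flagged `lambda_unidentifiable` and equals ordinary least squares.
#'
#' @param data species-keyed trait table with a `species` column.
#' @param spec a gaussian [model_spec()].
#' @param tree rooted `phylo` with branch lengths covering the species.
#' @param lambda optional fixed lambda in `[0, 1]`; `NULL` (default)
#'   estimates it by ML.
#' @return an object of class `pgls_fit`.
#' @export
fit_pgls <- function(data, spec, tree, lambda = NULL) {
  if (spec$family != "gaussian")
    stop("fit_pgls requires a gaussian model_spec")
  mf <- .build_model_frame(data, spec, tree)
  fit_pgls_core(mf$y, mf$X, mf$C, lambda = lambda,
                species = mf$species, spec = spec, dropped = mf$dropped)
}

#' @rdname fit_pgls
#' @param y,X,C response, design and phylogenetic covariance, already
#'   aligned (lower-level interface used by the simulation tests).
#' @param species optional species labels for bookkeeping.
#' @param dropped species removed by listwise deletion.
#' @export
fit_pgls_core <- function(y, X, C, lambda = NULL, species = NULL,
                          spec = NULL, dropped = character(0)) {
  X <- as.matrix(X)
  prof <- .profile_closure(y, X, C)
  unident <- FALSE
  if (is.null(lambda)) {
    probe <- vapply(c(0, 0.5, 1), prof, numeric(1))
    if (all(is.finite(probe)) && (max(probe) - min(probe)) < 1e-7) {
      unident <- TRUE
      lambda_hat <- 0
    } else {
      cand_lam <- c(0, 1)
      cand_ll <- vapply(cand_lam, prof, numeric(1))
      for (s in c(0.1, 0.5, 0.9)) {
        op <- stats::optim(s, function(l) -prof(l), method = "L-BFGS-B",
                           lower = 0, upper = 1,
                           control = list(factr = 1e5))
        cand_lam <- c(cand_lam, op$par)
        cand_ll <- c(cand_ll, -op$value)
      }
      best <- max(cand_ll)
      lambda_hat <- min(cand_lam[cand_ll >= best - 1e-8])
    }
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
    lambda_hat <- lambda
  }
  g <- gls_fit(y, X, lambda_transform(C, lambda_hat))
  structure(list(coefficients = g$beta, se = g$se, t = g$t, p = g$p,
                 lambda_hat = lambda_hat,
                 lambda_unidentifiable = unident,
                 sigma2_hat = g$sigma2_hat, loglik = g$loglik,
                 rss = g$rss, r_squared = g$r_squared,
                 n = g$n, df_resid = g$df_resid,
                 fitted = g$fitted, residuals = g$residuals,
                 species = species, spec = spec, dropped = dropped,
                 family = "gaussian"),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda, ML)\n")
  if (!is.null(x$spec))
    cat("  model: ", x$spec$outcome, " ~ ",
        paste(c(x$spec$focal_predictor, x$spec$covariates), collapse = " + "),
        "\n", sep = "")
  cat("  n =", x$n, " df =", x$df_resid,
      " lambda =", formatC(x$lambda_hat, digits = 4, format = "f"),
      if (x$lambda_unidentifiable) "(unidentifiable)" else "", "\n")
  tab <- cbind(Estimate = x$coefficients, SE = x$se, t = x$t, p = x$p)
  print(round(tab, 6))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients
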