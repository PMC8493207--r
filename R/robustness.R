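#' Refit one model over a block of trees
#'
#' Propagates phylogenetic uncertainty by refitting the same model on every
#' tree of a block. Per term it reports the median coefficient, percentile
#' 95% confidence interval (2.5% and 97.5% quantiles with linear
#' interpolation, R quantile type 7; medians likewise), the median Wald
#' statistic with its degrees of freedom, and the partial R-squared
#' computed from that median statistic. Lambda (or the logistic signal
#' strength) is re-estimated on every tree. A term is marked significant
#' when the two-sided p-value of its median statistic is below `alpha`.
#'
#' Single-tree fit failures are caught, recorded by tree index, and
#' excluded; the run aborts when more than `max_fail_frac` of the block
#' fails.
#'
#' @param data species-keyed trait table.
#' @param spec a [model_spec()].
#' @param block a `multiPhylo` or list of trees over the model's species.
#' @param alpha significance level for the per-term flag.
#' @param max_fail_frac abort threshold for the fraction of failed trees.
#' @return a `treeblock_summary`: one row per term with columns
#'   `term`, `median_beta`, `ci95_low`, `ci95_high`, `median_stat`,
#'   `df_median`, `partial_r2`, `sign`, `p_median`, `significant`; the
#'   number of trees used, failures and the family are attributes.
#' @export
fit_over_treeblock <- function(data, spec, block, alpha = 0.05,
                               max_fail_frac = 0.05) {
  if (inherits(block, "phylo")) block <- list(block)
  k <- length(block)
  if (k < 1L) stop("tree block is empty")
  fits <- vector("list", k)
  failed <- integer(0)
  for (i in seq_len(k)) {
    fits[[i]] <- tryCatch(fit_model(data, spec, block[[i]]),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) failed <- c(failed, i)
  }
  if (length(failed) > max_fail_frac * k)
    stop("tree-block fitting aborted: ", length(failed), " of ", k,
         " trees failed (first error: ",
         conditionMessage(fits[[failed[1]]]), ")", call. = FALSE)
  ok <- setdiff(seq_len(k), failed)
  fits <- fits[ok]
  gaussian <- spec$family == "gaussian"
  terms <- names(fits[[1]]$coefficients)
  B <- t(vapply(fits, function(f) f$coefficients, numeric(length(terms))))
  S <- t(vapply(fits, function(f) if (gaussian) f$t else f$z,
                numeric(length(terms))))
  df <- vapply(fits, function(f) f$df_resid, numeric(1))
  colnames(B) <- colnames(S) <- terms

  med <- function(x) stats::median(x)            # type-7 interpolation
  qs <- function(x, pr) stats::quantile(x, pr, names = FALSE, type = 7)
  df_median <- med(df)
  out <- data.frame(
    term = terms,
    median_beta = apply(B, 2, med),
    ci95_low = apply(B, 2, qs, 0.025),
    ci95_high = apply(B, 2, qs, 0.975),
    median_stat = apply(S, 2, med),
    df_median = df_median,
    stringsAsFactors = FALSE, row.names = NULL)
  out$partial_r2 <- partial_r2(out$median_stat, out$df_median)
  out$sign <- ifelse(out$median_beta >= 0, "+", "-")
  out$p_median <- if (gaussian)
    2 * stats::pt(-abs(out$median_stat), out$df_median)
  else 2 * stats::pnorm(-abs(out$median_stat))
  out$significant <- out$p_median < alpha
  structure(out, class = c("treeblock_summary", "data.frame"),
            n_trees = length(ok), n_failed = length(failed),
            failed_trees = failed, family = spec$family, spec = spec,
            per_tree_beta = B, per_tree_stat = S)
}

#' @export
print.treeblock_summary <- function(x, ...) {
  cat("Tree-block summary over", attr(x, "n_trees"), "trees")
  if (attr(x, "n_failed") > 0)
    cat(" (", attr(x, "n_failed"), " failed, excluded)", sep = "")
  cat("\n")
  print.data.frame(cbind(x[, c("term", "median_beta", "ci95_low",
                               "ci95_high", "median_stat")],
                         partial_r2 = round(x$partial_r2, 4),
                         sign = x$sign,
                         p = signif(x$p_median, 4),
                         sig = x$significant),
                   row.names = FALSE, digits = 5)
  invisible(x)
}

#' Leave-one-out influence diagnostics
#'
#' Removes each species in turn, refits the model (lambda or signal
#' strength re-estimated on the pruned tree each time), and records the
#' focal-term slope, intercept and p-value without that species. The
#' standardized difference of species i is
#' `(beta_full - beta_without_i) / SD_j(beta_without_j)`, the change in the
#' focal slope scaled by the spread of the leave-one-out estimates; a
#' species is flagged influential when its absolute standardized
#' difference exceeds `threshold` (default 2). When the leave-one-out
#' estimates have zero spread all standardized differences are defined as
#' zero and nothing is flagged.
#'
#' @param data species-keyed trait table.
#' @param spec a [model_spec()].
#' @param tree rooted `phylo` covering the species.
#' @param threshold flag threshold on `|sdiff|`.
#' @param term coefficient tracked; defaults to the focal predictor.
#' @return an `influence_report`: one row per species with `beta_loo`,
#'   `intercept_loo`, `p_loo`, `sdiff`, `influential`; the full-model
#'   coefficient and threshold are attributes.
#' @export
leave_one_out_influence <- function(data, spec, tree, threshold = 2,
                                    term = NULL) {
  if (is.null(term)) term <- spec$focal_predictor
  full <- fit_model(data, spec, tree)
  species <- full$species
  n <- length(species)
  p <- length(full$coefficients)
  if (n < p + 3L)
    stop("need at least p + 3 species so every deletion stays fittable")
  data <- as.data.frame(data)
  data$species <- normalize_taxa(data$species)
  beta_loo <- intercept_loo <- p_loo <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sub <- data[data$species != species[i], , drop = FALSE]
    f <- tryCatch(fit_model(sub, spec, tree), error = function(e) e)
    if (inherits(f, "error"))
      stop("model unfittable after removing species '", species[i],
           "': ", conditionMessage(f), call. = FALSE)
    beta_loo[i] <- f$coefficients[[term]]
    intercept_loo[i] <- f$coefficients[[1]]
    p_loo[i] <- f$p[[term]]
  }
  std_diff <- function(full_val, loo_vals) {
    s <- stats::sd(loo_vals)
    if (is.na(s) || s < 1e-12) rep(0, n) else (full_val - loo_vals) / s
  }
  full_beta <- full$coefficients[[term]]
  sdiff <- std_diff(full_beta, beta_loo)
  ## per-term hook: the intercept is recalculated alongside the slope
  sdiff_intercept <- std_diff(full$coefficients[[1]], intercept_loo)
  out <- data.frame(species = species, beta_loo = beta_loo,
                    intercept_loo = intercept_loo, p_loo = p_loo,
                    sdiff = sdiff, sdiff_intercept = sdiff_intercept,
                    influential = abs(sdiff) > threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("influence_report", "data.frame"),
            full_beta = full_beta, full_p = full$p[[term]],
            term = term, threshold = threshold)
}

#' @export
print.influence_report <- function(x, ...) {
  cat("Leave-one-out influence on '", attr(x, "term"), "' (full slope ",
      formatC(attr(x, "full_beta"), digits = 5), ", threshold ",
      attr(x, "threshold"), ")\n", sep = "")
  flagged <- x[x$influential, , drop = FALSE]
  if (nrow(flagged) == 0) cat("No influential species.\n")
  else print.data.frame(flagged, row.names = FALSE, digits = 5)
  invisible(x)
}
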