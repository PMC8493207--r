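## A characteristic is treated as binary when its observed values are all
## 0/1; binary responses go through the phylogenetic logistic model,
## continuous ones through PGLS.
.is_binary_col <- function(v) {
  v <- v[!is.na(v)]
  length(v) > 0 && all(v %in% c(0, 1)) && length(unique(v)) == 2L
}

#' Screen captive-population characteristics for confounding
#'
#' For every (predictor, characteristic) pair, regresses the
#' characteristic on the predictor under the appropriate phylogenetic
#' model (PGLS for continuous characteristics, phylogenetic logistic
#' regression for binary ones). Characteristics significantly associated
#' with a predictor (`p < alpha` on the predictor term) are confounds:
#' they map into that predictor's covariate set and are carried into the
#' corresponding hypothesis-testing models.
#'
#' @param data species-keyed trait table.
#' @param predictors character vector of predictor columns.
#' @param characteristics character vector of captive-population
#'   characteristic columns.
#' @param tree rooted `phylo` (typically the consensus tree).
#' @param alpha significance level (default 0.05).
#' @return named list: predictor -> character vector of screened-in
#'   characteristics; attribute `table` holds every pairwise p-value.
#' @export
screen_confounds <- function(data, predictors, characteristics, tree,
                             alpha = 0.05) {
  out <- stats::setNames(vector("list", length(predictors)), predictors)
  rows <- list()
  for (pr in predictors) {
    kept <- character(0)
    for (ch in characteristics) {
      binary <- .is_binary_col(data[[ch]])
      spec <- model_spec(outcome = ch, focal_predictor = pr,
                         family = if (binary) "binomial" else "gaussian")
      fit <- tryCatch(fit_model(data, spec, tree), error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(predictor = pr, characteristic = ch, p = NA_real_,
                     error = conditionMessage(fit), stringsAsFactors = FALSE)
        next
      }
      pv <- fit$p[[pr]]
      rows[[length(rows) + 1L]] <-
        data.frame(predictor = pr, characteristic = ch, p = pv,
                   error = "", stringsAsFactors = FALSE)
      if (is.finite(pv) && pv < alpha) kept <- c(kept, ch)
    }
    out[[pr]] <- kept
  }
  attr(out, "table") <- do.call(rbind, rows)
  out
}

#' Screen predictors for collinearity
#'
#' Pairwise phylogenetic regressions among the hypothesis predictors.
#' Significant pairs are reported so the hypothesis battery can include
#' the partner predictor as a covariate where collinearity could
#' artefactually create or mask an effect.
#'
#' @inheritParams screen_confounds
#' @return data.frame with one row per ordered-free pair: `predictor_a`,
#'   `predictor_b`, `p`, `flagged`.
#' @export
screen_collinearity <- function(data, predictors, tree, alpha = 0.05) {
  rows <- list()
  if (length(predictors) >= 2L) {
    cmb <- utils::combn(predictors, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      ## regress b on a; a binary member becomes the outcome so the
      ## logistic path handles it
      out_col <- b; pred_col <- a
      if (.is_binary_col(data[[a]]) && !.is_binary_col(data[[b]])) {
        out_col <- a; pred_col <- b
      }
      binary <- .is_binary_col(data[[out_col]])
      spec <- model_spec(outcome = out_col, focal_predictor = pred_col,
                         family = if (binary) "binomial" else "gaussian")
      fit <- tryCatch(fit_model(data, spec, tree), error = function(e) e)
      pv <- if (inherits(fit, "error")) NA_real_ else fit$p[[pred_col]]
      rows[[length(rows) + 1L]] <-
        data.frame(predictor_a = a, predictor_b = b, p = pv,
                   flagged = is.finite(pv) && pv < alpha,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(predictor_a = character(0),
                      predictor_b = character(0),
                      p = numeric(0), flagged = logical(0)))
  do.call(rbind, rows)
}
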