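#' Specify one comparative regression model
#'
#' A model specification names the outcome, the focal predictor whose
#' effect is under test, any covariates (controls), and the response
#' family. Binomial models need either a 0/1 outcome or a column of
#' denominators (`trials_column`) when the outcome column holds success
#' counts.
#'
#' @param outcome outcome column name.
#' @param focal_predictor column name of the predictor under test.
#' @param covariates character vector of control column names.
#' @param family `"gaussian"` (PGLS) or `"binomial"` (phylogenetic logistic
#'   regression).
#' @param trials_column for binomial models with count outcomes, the column
#'   holding the number of trials per species.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome, focal_predictor, covariates = character(0),
                       family = c("gaussian", "binomial"),
                       trials_column = NULL) {
  family <- match.arg(family)
  covariates <- as.character(covariates)
  if (focal_predictor %in% covariates)
    stop("focal predictor '", focal_predictor,
         "' must not appear among the covariates")
  if (outcome %in% c(focal_predictor, covariates))
    stop("outcome '", outcome, "' must not appear among the predictors")
  structure(list(outcome = outcome,
                 focal_predictor = focal_predictor,
                 covariates = covariates,
                 family = family,
                 trials_column = trials_column),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- paste(c(x$focal_predictor, x$covariates), collapse = " + ")
  cat("model_spec [", x$family, "]: ", x$outcome, " ~ ", rhs, "\n", sep = "")
  if (!is.null(x$trials_column))
    cat("  trials column:", x$trials_column, "\n")
  invisible(x)
}

## Listwise deletion, alignment of data to the pruned tree, design matrix
## construction. The covariance is ordered by data row, not tip order.
.build_model_frame <- function(data, spec, tree) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  if (!"species" %in% names(data))
    stop("data must contain a 'species' column")
  data$species <- normalize_taxa(data$species)
  used <- c(spec$outcome, spec$focal_predictor, spec$covariates,
            spec$trials_column)
  absent <- setdiff(used, names(data))
  if (length(absent))
    stop("column(s) absent from data: ", paste(absent, collapse = ", "))
  for (cl in used) {
    if (!is.numeric(data[[cl]]))
      stop("column '", cl, "' must be numeric")
  }
  ok <- stats::complete.cases(data[used])
  dropped <- data$species[!ok]
  data <- data[ok, , drop = FALSE]
  bad <- !vapply(seq_len(nrow(data)),
                 function(i) all(is.finite(as.numeric(data[i, used]))),
                 logical(1))
  if (any(bad))
    stop("non-finite values for species: ",
         paste(data$species[bad], collapse = ", "))
  p <- 1L + 1L + length(spec$covariates)
  if (nrow(data) < p + 2L)
    stop("too few species after listwise deletion: ", nrow(data),
         " retained, need at least ", p + 2L)
  tree <- .validate_phylo(tree)
  miss <- setdiff(data$species, tree$tip.label)
  if (length(miss))
    stop("species absent from tree: ", paste(miss, collapse = ", "))
  tree <- prune_to_taxa(tree, data$species)
  C <- phylo_covariance(tree, taxa_order = data$species)
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[, c(spec$focal_predictor, spec$covariates),
                            drop = FALSE]))
  y <- data[[spec$outcome]]
  trials <- if (!is.null(spec$trials_column)) data[[spec$trials_column]]
  list(y = y, X = X, C = C, species = data$species, tree = tree,
       trials = trials, dropped = dropped)
}

#' Fit one comparative model (family dispatch)
#'
#' Convenience wrapper calling [fit_pgls()] for gaussian specifications and
#' [fit_phylo_logistic()] for binomial ones.
#'
#' @param data species-keyed trait table with a `species` column.
#' @param spec a [model_spec()].
#' @param tree a rooted `phylo` covering the species.
#' @param ... passed to the family-specific fitter.
#' @return a `pgls_fit` or `phylo_logistic_fit`.
#' @export
fit_model <- function(data, spec, tree, ...) {
  if (spec$family == "gaussian") fit_pgls(data, spec, tree, ...)
  else fit_phylo_logistic(data, spec, tree, ...)
}
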