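#' Assemble the hypothesis battery
#'
#' Builds one [model_spec()] per predictor-by-outcome cell, attaching the
#' mandated controls: body mass in every brain-volume model (allometry),
#' research effort in every innovation model, natural fecundity in every
#' hatch-rate model. Captive-population characteristics screened in by
#' [screen_confounds()] join the covariates of their predictor's
#' stereotypic-behaviour models, and predictors flagged by
#' [screen_collinearity()] join each other's models as covariates. The
#' aviculture population-size predictor is only paired with the hatch-rate
#' outcome.
#'
#' @param outcomes character vector of outcome columns (prevalence columns
#'   and/or `hatch_rate`).
#' @param predictors character vector of focal predictor columns.
#' @param screened named list predictor -> screened-in characteristics
#'   (from [screen_confounds()]).
#' @param collinear data.frame from [screen_collinearity()]; flagged
#'   partners become covariates.
#' @param family family for prevalence outcomes: `"gaussian"` analyses the
#'   proportion scale by PGLS, `"binomial"` uses the phylogenetic logistic
#'   model on success counts (then `trials_column` and `count_columns`
#'   name the denominators and per-outcome count columns).
#' @param trials_column denominator column for binomial prevalence models.
#' @param count_columns named map outcome -> success-count column for
#'   binomial prevalence models.
#' @return a `hypothesis_battery`: list of `model_spec`s.
#' @export
assemble_battery <- function(outcomes, predictors, screened = list(),
                             collinear = NULL,
                             family = c("gaussian", "binomial"),
                             trials_column = NULL, count_columns = NULL) {
  family <- match.arg(family)
  specs <- list()
  for (out in outcomes) {
    hatch <- identical(out, "hatch_rate")
    for (pr in predictors) {
      if (pr == "n_pairs_aviculture" && !hatch) next
      cov <- character(0)
      if (pr == "brain_volume_ml") cov <- c(cov, "body_mass_g")
      if (pr == "innovation_count") cov <- c(cov, "research_effort_papers")
      if (hatch) cov <- c(cov, "natural_fecundity")
      if (!hatch && pr %in% names(screened))
        cov <- c(cov, screened[[pr]])
      if (!is.null(collinear) && nrow(collinear)) {
        fl <- collinear[collinear$flagged, , drop = FALSE]
        partners <- c(fl$predictor_b[fl$predictor_a == pr],
                      fl$predictor_a[fl$predictor_b == pr])
        partners <- setdiff(partners,
                            if (hatch) character(0) else "n_pairs_aviculture")
        cov <- c(cov, partners)
      }
      cov <- setdiff(unique(cov), c(pr, out))
      if (family == "binomial" && !hatch) {
        ycol <- if (!is.null(count_columns) && out %in% names(count_columns))
          count_columns[[out]] else out
        specs[[length(specs) + 1L]] <-
          model_spec(ycol, pr, cov, family = "binomial",
                     trials_column = trials_column)
      } else {
        specs[[length(specs) + 1L]] <- model_spec(out, pr, cov,
                                                  family = "gaussian")
      }
      attr(specs[[length(specs)]], "cell") <- c(outcome = out, predictor = pr)
    }
  }
  structure(specs, class = "hypothesis_battery")
}

#' Validate a hypothesis battery
#'
#' Enforces the battery invariants: every brain-volume model controls for
#' body mass, every innovation model for research effort, and every
#' hatch-rate model for natural fecundity. Violations name the offending
#' cell and refuse to run.
#'
#' @param battery a `hypothesis_battery` (or list of `model_spec`s).
#' @return the battery, invisibly, when valid.
#' @export
validate_battery <- function(battery) {
  for (spec in battery) {
    cell <- paste0(spec$outcome, " ~ ", spec$focal_predictor)
    if (spec$focal_predictor == "brain_volume_ml" &&
        !"body_mass_g" %in% spec$covariates)
      stop("battery invariant violated (", cell,
           "): brain-volume models must include body_mass_g")
    if (spec$focal_predictor == "innovation_count" &&
        !"research_effort_papers" %in% spec$covariates)
      stop("battery invariant violated (", cell,
           "): innovation models must include research_effort_papers")
    out <- if (!is.null(attr(spec, "cell"))) attr(spec, "cell")[["outcome"]]
           else spec$outcome
    if (identical(out, "hatch_rate") &&
        !"natural_fecundity" %in% spec$covariates)
      stop("battery invariant violated (", cell,
           "): hatch-rate models must include natural_fecundity")
  }
  invisible(battery)
}

## Outcome transform for prevalence models, selectable in the config
## because proportion outcomes admit several conventions.
.transform_outcome <- function(p, transform, eps = 0.01) {
  switch(transform,
         none = p,
         logit = stats::qlogis(pmin(pmax(p, eps), 1 - eps)),
         arcsine = asin(sqrt(p)),
         stop("unknown outcome transform: ", transform))
}

#' Run the hypothesis battery
#'
#' The end-to-end hypothesis test: each cell of the battery is refit over
#' the tree block ([fit_over_treeblock()]) and, per the configured policy,
#' leave-one-out influence diagnostics run on the consensus tree. Returns
#' the Table-2-shaped results table (sign, significance, partial
#' R-squared from the median statistic, 95% percentile CIs) plus the full
#' per-cell objects, under the run's configuration hash.
#'
#' @param data species-keyed trait table.
#' @param battery a validated `hypothesis_battery`.
#' @param consensus consensus `phylo` used for influence diagnostics.
#' @param block `multiPhylo` tree block.
#' @param config configuration list (see [default_config()]).
#' @param exclusions optional exclusion records carried into the outputs.
#' @return a `ppcm_results` object.
#' @export
run_battery <- function(data, battery, consensus, block,
                        config = default_config(), exclusions = NULL) {
  validate_battery(battery)
  data <- validate_species_data(data)
  transform <- config$outcome$transform
  alpha <- config$model$alpha
  rows <- list()
  summaries <- list()
  influence <- list()
  for (k in seq_along(battery)) {
    spec <- battery[[k]]
    cell <- attr(spec, "cell")
    out_name <- if (!is.null(cell)) cell[["outcome"]] else spec$outcome
    pred <- spec$focal_predictor
    dat_k <- data
    if (spec$family == "gaussian" && grepl("^prevalence_", spec$outcome) &&
        transform != "none")
      dat_k[[spec$outcome]] <- .transform_outcome(dat_k[[spec$outcome]],
                                                  transform)
    key <- paste0(out_name, "__", pred)
    summ <- fit_over_treeblock(dat_k, spec, block, alpha = alpha)
    focal <- summ[summ$term == pred, , drop = FALSE]
    want_influ <- switch(config$influence$cells,
                         all = TRUE,
                         none = FALSE,
                         significant = isTRUE(focal$significant))
    if (want_influ) {
      influence[[key]] <- leave_one_out_influence(
        dat_k, spec, consensus, threshold = config$influence$threshold)
    }
    summaries[[key]] <- summ
    rows[[k]] <- data.frame(
      outcome = out_name, predictor = pred,
      covariates = paste(spec$covariates, collapse = ","),
      family = spec$family, n_trees = attr(summ, "n_trees"),
      median_beta = focal$median_beta, ci95_low = focal$ci95_low,
      ci95_high = focal$ci95_high, median_stat = focal$median_stat,
      df_median = focal$df_median, partial_r2 = focal$partial_r2,
      sign = focal$sign, p_median = focal$p_median,
      significant = focal$significant,
      n_influential = if (want_influ) sum(influence[[key]]$influential)
                      else NA_integer_,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), summaries = summaries,
                 influence = influence, exclusions = exclusions,
                 config_hash = config_hash(config),
                 seed = config$seed, n_trees = length(block)),
            class = "ppcm_results")
}

#' @export
print.ppcm_results <- function(x, ...) {
  cat("ppcm hypothesis-battery results (", nrow(x$table), " cells, ",
      x$n_trees, " trees, config ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  tab <- x$table
  tab$partial_r2 <- round(tab$partial_r2, 3)
  tab$median_beta <- signif(tab$median_beta, 4)
  print.data.frame(tab[, c("outcome", "predictor", "sign", "partial_r2",
                           "median_beta", "p_median", "significant")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write battery results to disk
#'
#' Emits `results_table.tsv` (the Table-2-shaped summary),
#' `results.json` (full per-cell fits), one `influence/<cell>.tsv` per
#' influence report, `exclusions.log`, and `run.log` with the
#' configuration hash and seed. Identical inputs, configuration and seed
#' produce byte-identical outputs.
#'
#' @param results a `ppcm_results`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- results$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 10))
  utils::write.table(tab, file.path(out_dir, "results_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    config_hash = results$config_hash, seed = results$seed,
    n_trees = results$n_trees, table = results$table,
    summaries = lapply(results$summaries, function(s) {
      as.list(s[, c("term", "median_beta", "ci95_low", "ci95_high",
                    "median_stat", "df_median", "partial_r2", "sign",
                    "p_median", "significant")])
    }),
    influence = lapply(results$influence, function(ir)
      as.list(ir[, c("species", "beta_loo", "p_loo", "sdiff",
                     "influential")])))
  writeLines(jsonlite::toJSON(payload, digits = 12, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(out_dir, "results.json"))
  influ_dir <- file.path(out_dir, "influence")
  dir.create(influ_dir, showWarnings = FALSE)
  for (key in names(results$influence)) {
    ir <- results$influence[[key]]
    ir_out <- as.data.frame(ir)
    ir_out[vapply(ir_out, is.numeric, logical(1))] <-
      lapply(ir_out[vapply(ir_out, is.numeric, logical(1))],
             function(v) signif(v, 10))
    utils::write.table(ir_out, file.path(influ_dir, paste0(key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_exclusions(results$exclusions, file.path(out_dir, "exclusions.log"))
  writeLines(c(paste0("config_hash: ", results$config_hash),
               paste0("seed: ", results$seed),
               paste0("n_trees: ", results$n_trees),
               paste0("cells: ", nrow(results$table))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
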