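#' Default run configuration
#'
#' The full configuration tree with every documented default: quality
#' filters (`min_individuals_per_species`, `min_pairs_per_species`),
#' screening alpha, the consensus method, the outcome transform for
#' prevalence models (`none`, `logit` or `arcsine`), survey-size weighting
#' (off by default), the influence-diagnostic policy and threshold, and
#' the simulation block. User configurations (YAML) override these
#' defaults key by key.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(species_table = NULL, consensus_tree = NULL,
                 tree_block = NULL, out_dir = "ppcm_results"),
    filters = list(min_individuals_per_species = 5,
                   min_pairs_per_species = 1),
    screening = list(alpha = 0.05),
    consensus = list(method = "majority", p = 0.5),
    outcome = list(transform = "none"),
    model = list(weight_by_sample_size = FALSE, alpha = 0.05),
    influence = list(cells = "significant", threshold = 2),
    simulation = list(n_species = 50, tree_model = "birth_death",
                      lambda_true = 1, sigma2_true = 1,
                      n_individuals = c(5, 50), n_trees_block = 1000,
                      jitter = 0.1)
  )
}

## Recursive override of defaults by user values.
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Loads a YAML file and merges it over [default_config()]. The returned
#' list carries a `hash` attribute: the MD5 of the canonical serialized
#' configuration, recorded in run logs so outputs are traceable to the
#' exact configuration that produced them.
#'
#' @param file path to a YAML file, or `NULL` for pure defaults.
#' @return configuration list with attribute `hash`.
#' @export
read_run_config <- function(file = NULL) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    user <- yaml::read_yaml(file)
    if (!is.list(user)) stop("config file must hold a YAML mapping")
    cfg <- .merge_config(cfg, user)
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
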