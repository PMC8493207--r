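#' Simulate a full study-shaped comparative dataset
#'
#' Generates a dataset with the column layout the pipeline analyses end to
#' end: sociality, foraging-style, generalism, intelligence and rarity
#' predictors; allometry/research-effort/fecundity controls;
#' captive-population characteristics available for confound screening;
#' binomial stereotypic-behaviour prevalences with per-species survey
#' sizes; and a hatch-rate outcome with pair counts. Continuous predictors
#' carry phylogenetic signal (built from Brownian latents on the tree);
#' diet percentages come from a softmax over Brownian latents and are
#' collapsed through [derive_diet_features()]; brain volume follows an
#' allometric line on body mass. All effects are null unless `effects`
#' plants them.
#'
#' @param cfg a [sim_config()].
#' @param effects named list: outcome column -> named numeric of true
#'   slopes per predictor, applied on the standardized predictor scale
#'   (e.g. `list(prevalence_fdb = c(pct_diet_handling = 0.5))`).
#' @return list with `data` (trait table), `tree` (the base phylogeny) and
#'   `block` (the jittered tree block).
#' @export
simulate_study <- function(cfg, effects = list()) {
  tree <- simulate_tree(cfg)
  block <- simulate_treeblock(tree, cfg = cfg)
  set.seed(.substream(cfg$seed, "study"))
  n <- cfg$n_species
  C <- phylo_covariance(tree)
  Rlam <- stats::cov2cor(lambda_transform(C, cfg$lambda_true))

  bm <- function() as.numeric(scale(.rbm(C, 1)))   # standardized BM latent
  ## diet composition: softmax over six Brownian latents
  cats <- c("invertebrates", "nectar_pollen", "fruit", "tree_seeds",
            "grass_seeds", "other")
  D <- vapply(cats, function(cl) exp(1.2 * bm()), numeric(n))
  D <- 100 * D / rowSums(D)
  diet <- t(vapply(seq_len(n), function(i)
    derive_diet_features(as.list(stats::setNames(D[i, ], cats))),
    numeric(2)))

  body_mass <- exp(log(300) + 1.0 * bm())
  brain <- exp(-2 + 0.6 * log(body_mass) + 0.25 * bm())
  research <- pmax(0, round(exp(2.5 + 1.0 * bm())))
  innovation <- stats::rpois(n, exp(0.2 + 0.6 * scale(log1p(research)) +
                                      0.5 * bm()))
  fecundity <- natural_fecundity(exp(stats::rnorm(n, log(4), 0.3)),
                                 exp(stats::rnorm(n, log(1.5), 0.3)))
  data <- data.frame(
    species = tree$tip.label,
    max_feeding_group_size = pmax(1, round(exp(1.5 + 1.2 * bm()))),
    communal_roosting = as.integer(bm() > 0),
    pct_diet_search = diet[, "pct_search"],
    pct_diet_handling = diet[, "pct_handling"],
    diet_breadth = pmin(5, pmax(1, ceiling(5 * stats::plogis(bm())))),
    habitat_breadth = pmin(7, pmax(1, ceiling(7 * stats::plogis(bm())))),
    innovation_count = innovation,
    brain_volume_ml = brain,
    iucn_rank = pmin(5, pmax(1, ceiling(5 * stats::plogis(bm() - 1)))),
    n_pairs_aviculture = round(exp(stats::runif(n, log(1), log(500)))),
    body_mass_g = body_mass,
    research_effort_papers = research,
    natural_fecundity = fecundity,
    prop_standard_cage = stats::plogis(bm()),
    prop_hand_reared = stats::plogis(bm()),
    enrichment_diversity = pmax(0, round(2 + 1.5 * bm())),
    stringsAsFactors = FALSE, row.names = NULL)

  n_surv <- sample(seq(cfg$n_individuals[1], cfg$n_individuals[2]),
                   n, replace = TRUE)
  data$n_surveyed <- n_surv
  lin_for <- function(out_name) {
    eff <- effects[[out_name]]
    lp <- numeric(n)
    for (pr in names(eff)) {
      if (!pr %in% names(data)) stop("effect on unknown predictor: ", pr)
      lp <- lp + eff[[pr]] * as.numeric(scale(data[[pr]]))
    }
    lp
  }
  bases <- c(prevalence_fdb = cfg$base_prevalence,
             prevalence_oral_sb = cfg$base_prevalence,
             prevalence_wholebody_sb = 0.23)
  for (out_name in names(bases)) {
    latent <- stats::qlogis(bases[[out_name]]) + lin_for(out_name) +
      cfg$latent_sd * as.numeric(.rbm(Rlam, 1))
    aff <- stats::rbinom(n, n_surv, stats::plogis(latent))
    data[[sub("prevalence", "affected", out_name)]] <- aff
    data[[out_name]] <- aff / n_surv
  }
  hatch <- 0.3 * fecundity + lin_for("hatch_rate") +
    0.25 * as.numeric(.rbm(Rlam, 1))
  data$hatch_rate <- pmax(0, hatch)
  list(data = validate_species_data(data), tree = tree, block = block)
}
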