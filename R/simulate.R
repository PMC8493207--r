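#' Simulation configuration
#'
#' Ground-truth settings for the synthetic comparative datasets. Defaults
#' mirror the shape of the study system the package targets: a 50-species
#' survey arm with 5-50 individuals surveyed per species (about 1400
#' individuals in total), baseline prevalences near 20%, full Brownian
#' signal, and a 1000-tree block for uncertainty propagation. The breeding
#' arm is emulated by raising `n_species` (115 in the study) with pairs
#' drawn log-uniformly on 1-500.
#'
#' @param n_species number of tips (`>= 3`).
#' @param tree_model `"birth_death"` (ultrametric birth-death),
#'   `"coalescent"` or `"star"`.
#' @param lambda_true residual phylogenetic signal of simulated outcomes.
#' @param sigma2_true residual rate of the gaussian outcome.
#' @param slopes named numeric: predictors to generate (as Brownian
#'   traits) and their true effects on the outcomes.
#' @param n_individuals length-2 range of per-species survey sizes.
#' @param n_trees_block number of trees in the simulated block.
#' @param jitter log-normal SD of branch-length jitter in the block.
#' @param outlier optional `list(species =, displacement =)` planted after
#'   trait simulation.
#' @param base_prevalence baseline outcome prevalence (logit intercept).
#' @param latent_sd SD of the latent phylogenetic noise on the logit scale.
#' @param seed integer seed (mandatory; all generators are pure functions
#'   of configuration and seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 50, tree_model = "birth_death",
                       lambda_true = 1, sigma2_true = 1,
                       slopes = c(x1 = 0), n_individuals = c(5, 50),
                       n_trees_block = 1000, jitter = 0.1, outlier = NULL,
                       base_prevalence = 0.2, latent_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_species >= 3, sigma2_true > 0,
            lambda_true >= 0, lambda_true <= 1,
            length(n_individuals) == 2, all(n_individuals >= 1),
            n_trees_block >= 1, jitter >= 0,
            base_prevalence > 0, base_prevalence < 1, latent_sd >= 0)
  if (is.null(names(slopes)) || any(!nzchar(names(slopes))))
    stop("slopes must be a named numeric vector")
  structure(list(n_species = as.integer(n_species),
                 tree_model = match.arg(tree_model,
                                        c("birth_death", "coalescent",
                                          "star")),
                 lambda_true = lambda_true, sigma2_true = sigma2_true,
                 slopes = slopes, n_individuals = n_individuals,
                 n_trees_block = as.integer(n_trees_block),
                 jitter = jitter, outlier = outlier,
                 base_prevalence = base_prevalence, latent_sd = latent_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## One global seed expanded into per-component substreams so components
## can be regenerated independently.
.substream <- function(seed, component) {
  offsets <- c(tree = 1, block = 2, traits = 3, study = 4)
  ## double arithmetic: products of 32-bit seeds overflow integer space
  as.integer((as.numeric(seed) * 7919 + offsets[[component]]) %%
               2147483646) + 1L
}

#' Simulate an ultrametric phylogeny
#'
#' Rooted ultrametric trees with total depth scaled to 1: birth-death
#' (`ape::rphylo`, birth 1, death 0.5), coalescent (`ape::rcoal`), or a
#' star phylogeny (all tips attached to the root with unit branch
#' lengths). Tips are labelled `sp001`, `sp002`, ...
#'
#' @param cfg a [sim_config()]; alternatively pass `n_species`,
#'   `tree_model`, `seed` directly.
#' @param n_species,tree_model,seed used when `cfg` is absent.
#' @return a `phylo`.
#' @export
simulate_tree <- function(cfg = NULL, n_species = 50,
                          tree_model = "birth_death", seed = 1) {
  if (!is.null(cfg)) {
    n_species <- cfg$n_species
    tree_model <- cfg$tree_model
    seed <- .substream(cfg$seed, "tree")
  }
  if (n_species < 3) stop("need at least 3 species")
  set.seed(seed)
  tr <- switch(tree_model,
               birth_death = ape::rphylo(n_species, birth = 1, death = 0.5),
               coalescent = ape::rcoal(n_species),
               star = {
                 s <- ape::stree(n_species, type = "star")
                 s$edge.length <- rep(1, nrow(s$edge))
                 s
               },
               stop("unknown tree model: ", tree_model))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Simulate a tree block around a base tree
#'
#' Emulates a distribution of equally plausible phylogenies: each block
#' member is the base tree with independent mean-corrected log-normal
#' branch-length jitter (multipliers `exp(sd*Z - sd^2/2)`, expectation 1,
#' so mean edge lengths match the base tree) and optionally `nni` random
#' nearest-neighbour-interchange topology moves (requires phangorn).
#'
#' @param base a `phylo`.
#' @param n_trees number of trees.
#' @param jitter log-normal SD of the length multipliers.
#' @param nni number of NNI moves per tree (0 = topology fixed).
#' @param seed integer seed.
#' @param cfg optional [sim_config()] supplying `n_trees_block`, `jitter`
#'   and the seed substream.
#' @return a `multiPhylo`.
#' @export
simulate_treeblock <- function(base, n_trees = 100, jitter = 0.1, nni = 0,
                               seed = 1, cfg = NULL) {
  if (!is.null(cfg)) {
    n_trees <- cfg$n_trees_block
    jitter <- cfg$jitter
    seed <- .substream(cfg$seed, "block")
  }
  base <- .validate_phylo(base)
  if (nni > 0 && !requireNamespace("phangorn", quietly = TRUE))
    stop("topology moves require the phangorn package")
  set.seed(seed)
  ne <- nrow(base$edge)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- base
    if (nni > 0) tr <- phangorn::rNNI(tr, moves = nni)
    if (jitter > 0)
      tr$edge.length <- tr$edge.length *
        exp(stats::rnorm(nrow(tr$edge), 0, jitter) - jitter^2 / 2)
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  attr(trees, "shared_taxa") <- sort(base$tip.label)
  trees
}

## Draw k independent Brownian traits on the tree: columns ~ MVN(0, C).
.rbm <- function(C, k = 1) {
  L <- chol(C)             # C = t(L) %*% L, L upper triangular
  Z <- matrix(stats::rnorm(nrow(C) * k), nrow(C), k)
  out <- crossprod(L, Z)   # columns ~ MVN(0, C)
  rownames(out) <- rownames(C)
  out
}

#' Simulate species traits with known ground truth
#'
#' Generates the statistical structure the comparative models assume:
#' predictors drawn as Brownian motions on the tree (one per named slope),
#' a gaussian outcome `y = X beta + eps` with
#' `eps ~ MVN(0, sigma2 * lambda-transformed C)`, and a binomial outcome
#' in which the per-species true prevalence is the inverse logit of the
#' same linear predictor (on the standardized predictor scale) plus
#' lambda-structured latent noise, observed as `affected ~
#' Binomial(n_surveyed, prevalence)`. Controls with realistic positive
#' skew (body mass, research effort, natural fecundity) are included.
#'
#' @param tree a `phylo`.
#' @param cfg a [sim_config()].
#' @param seed optional override of the traits substream.
#' @return a `data.frame` with attributes `resid_sd` (the true residual
#'   SD) and `true_slopes`.
#' @export
simulate_traits <- function(tree, cfg, seed = NULL) {
  tree <- .validate_phylo(tree)
  if (is.null(seed)) seed <- .substream(cfg$seed, "traits")
  set.seed(seed)
  n <- length(tree$tip.label)
  C <- phylo_covariance(tree)
  Vlam <- lambda_transform(C, cfg$lambda_true)
  preds <- names(cfg$slopes)
  Xp <- .rbm(C, length(preds))
  colnames(Xp) <- preds
  beta <- as.numeric(cfg$slopes)
  lin <- as.numeric(Xp %*% beta)
  y <- lin + as.numeric(.rbm(Vlam, 1)) * sqrt(cfg$sigma2_true)
  n_surv <- sample(seq(cfg$n_individuals[1], cfg$n_individuals[2]),
                   n, replace = TRUE)
  Z <- scale(Xp)
  latent <- qlogis(cfg$base_prevalence) + as.numeric(Z %*% beta) +
    cfg$latent_sd * as.numeric(.rbm(stats::cov2cor(
      lambda_transform(C, cfg$lambda_true)), 1))
  prev_true <- stats::plogis(latent)
  affected <- stats::rbinom(n, n_surv, prev_true)
  body_mass <- exp(stats::rnorm(n, log(300), 1))
  research <- round(exp(stats::rnorm(n, 2.5, 1)))
  fecundity <- natural_fecundity(exp(stats::rnorm(n, log(4), 0.3)),
                                 exp(stats::rnorm(n, log(1.5), 0.3)))
  out <- data.frame(species = tree$tip.label, Xp, y = y,
                    affected = affected, n_surveyed = n_surv,
                    prevalence = affected / n_surv,
                    body_mass_g = body_mass,
                    research_effort_papers = research,
                    natural_fecundity = fecundity,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(cfg$outlier))
    out <- plant_outlier(out, cfg$outlier$species,
                         cfg$outlier$displacement,
                         resid_sd = sqrt(cfg$sigma2_true))
  attr(out, "resid_sd") <- sqrt(cfg$sigma2_true)
  attr(out, "true_slopes") <- cfg$slopes
  out
}

#' Plant an outlier species
#'
#' Displaces one species' outcome by a given number of residual standard
#' deviations, to exercise the leave-one-out influence diagnostics with a
#' known answer. Provenance is recorded in the `"outlier"` attribute.
#'
#' @param data a species trait table.
#' @param species species label to displace.
#' @param displacement shift in residual SDs.
#' @param outcome outcome column (default `"y"`).
#' @param resid_sd residual SD; defaults to the generator's `resid_sd`
#'   attribute, else the sample SD of the outcome.
#' @return the modified data, with attribute `outlier`.
#' @export
plant_outlier <- function(data, species, displacement, outcome = "y",
                          resid_sd = NULL) {
  i <- match(normalize_taxa(species), normalize_taxa(data$species))
  if (is.na(i)) stop("unknown species: ", species)
  if (is.null(resid_sd))
    resid_sd <- attr(data, "resid_sd") %||% stats::sd(data[[outcome]])
  data[[outcome]][i] <- data[[outcome]][i] + displacement * resid_sd
  attr(data, "outlier") <- list(species = data$species[i],
                                displacement = displacement,
                                outcome = outcome, resid_sd = resid_sd)
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
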