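#' Per-species prevalence of a behavioural outcome
#'
#' Prevalence is the fraction of surveyed individuals showing the
#' behaviour. Species surveyed below `min_sample` individuals carry too
#' little information and are excluded: their prevalence is returned as
#' `NA` and the exclusion is reported through the `"excluded"` attribute
#' (species index, reason code `"below_min_sample"`), which the pipeline
#' writes to the exclusion log.
#'
#' @param affected number of affected individuals (vectorized).
#' @param surveyed number surveyed.
#' @param min_sample minimum individuals per species (default 5).
#' @return prevalences in `[0, 1]`, `NA` where excluded.
#' @export
compute_prevalence <- function(affected, surveyed, min_sample = 5) {
  if (length(affected) != length(surveyed))
    stop("affected and surveyed must have equal length")
  if (any(affected < 0) || any(surveyed < 0))
    stop("counts must be nonnegative")
  if (any(affected > surveyed))
    stop("affected exceeds surveyed at position ",
         paste(which(affected > surveyed), collapse = ", "))
  out <- ifelse(surveyed > 0, affected / surveyed, NA_real_)
  low <- surveyed < min_sample
  out[low] <- NA_real_
  if (any(low))
    attr(out, "excluded") <- data.frame(index = which(low),
                                        reason = "below_min_sample",
                                        stringsAsFactors = FALSE)
  out
}

#' Captive hatch rate
#'
#' Chicks hatched per breeding pair per year.
#'
#' @param chicks total chicks hatched.
#' @param pairs number of breeding pairs (`>= 1`).
#' @param years observation span in years (`> 0`).
#' @return chicks per pair per year.
#' @export
compute_hatch_rate <- function(chicks, pairs, years = 1) {
  if (any(pairs < 1)) stop("pairs must be >= 1")
  if (any(years <= 0)) stop("years must be > 0")
  if (any(chicks < 0)) stop("chicks must be nonnegative")
  chicks / (pairs * years)
}

#' Natural fecundity
#'
#' The species' reproductive potential in the wild: the product of the
#' median eggs per clutch and clutches per year. Used as the life-history
#' control in all hatch-rate models.
#'
#' @param eggs_per_clutch median clutch size (`> 0`).
#' @param clutches_per_year clutches per year (`> 0`).
#' @return eggs per year.
#' @export
natural_fecundity <- function(eggs_per_clutch, clutches_per_year) {
  if (any(eggs_per_clutch <= 0) || any(clutches_per_year <= 0))
    stop("eggs_per_clutch and clutches_per_year must be positive")
  eggs_per_clutch * clutches_per_year
}

#' Foraging-style percentages from a diet composition
#'
#' Collapses a species' diet composition (percent reliance per food
#' category) into the two foraging-constraint predictors: the percentage
#' of the natural diet requiring extensive locomotor/visual food search
#' (invertebrates, nectar and pollen, fruit, tree seeds/nuts) and the
#' percentage requiring extensive food handling (invertebrates and tree
#' seeds/nuts). Sources that pool tree seeds and grass seeds into a single
#' `seeds` entry must supply `seed_split_ratio` (tree : grass), used to
#' split the pooled percentage proportionally before the sums are taken.
#'
#' @param diet_pcts named numeric of percentages over the categories
#'   `invertebrates`, `nectar_pollen`, `fruit`, `tree_seeds`,
#'   `grass_seeds`, `other` (absent categories count as 0); alternatively
#'   a pooled `seeds` entry replacing the two seed categories.
#' @param seed_split_ratio length-2 numeric `c(tree, grass)` giving the
#'   proportional split of a pooled `seeds` entry.
#' @param tol allowed deviation of the percentage sum from 100.
#' @return named numeric `c(pct_search, pct_handling)`.
#' @export
derive_diet_features <- function(diet_pcts, seed_split_ratio = NULL,
                                 tol = 0.5) {
  known <- c("invertebrates", "nectar_pollen", "fruit", "tree_seeds",
             "grass_seeds", "other", "seeds")
  bad <- setdiff(names(diet_pcts), known)
  if (length(bad))
    stop("unknown diet categories: ", paste(bad, collapse = ", "))
  get <- function(nm) if (nm %in% names(diet_pcts)) diet_pcts[[nm]] else 0
  total <- sum(unlist(diet_pcts))
  if (abs(total - 100) > tol)
    stop("diet percentages sum to ", format(total), ", outside 100 +/- ",
         tol)
  tree_seeds <- get("tree_seeds")
  grass_seeds <- get("grass_seeds")
  if ("seeds" %in% names(diet_pcts)) {
    if (tree_seeds > 0 || grass_seeds > 0)
      stop("supply either pooled 'seeds' or split seed categories, not both")
    if (is.null(seed_split_ratio))
      stop("pooled 'seeds' entry requires seed_split_ratio (tree : grass)")
    if (length(seed_split_ratio) != 2L || any(seed_split_ratio < 0) ||
        sum(seed_split_ratio) <= 0)
      stop("seed_split_ratio must be two nonnegative numbers, not both zero")
    w <- seed_split_ratio / sum(seed_split_ratio)
    tree_seeds <- get("seeds") * w[1]
    grass_seeds <- get("seeds") * w[2]
  }
  pct_search <- get("invertebrates") + get("nectar_pollen") + get("fruit") +
    tree_seeds
  pct_handling <- get("invertebrates") + tree_seeds
  c(pct_search = pct_search, pct_handling = pct_handling)
}
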