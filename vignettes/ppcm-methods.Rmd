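---
title: "Phylogenetic comparative models for captive-welfare risk factors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ppcm methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcm)
```

## The problem

Species kept in captivity differ widely in how prone they are to
stereotypic behaviours (SB; e.g. feather-damaging behaviour, route-tracing)
and to poor captive reproduction. Species-level trait data — diet
composition, sociality, brain size, conservation status — can be screened
for risk factors, but species are not independent observations: close
relatives resemble each other because of shared descent. `ppcm` implements
the comparative-inference machinery for this setting: regressions whose
residual covariance follows the phylogeny, screening for confounds and
collinearity among predictors, propagation of phylogenetic uncertainty
over a block of candidate trees, and leave-one-out influence diagnostics —
plus a synthetic-data generator with known ground truth so that every
stage is testable without access to any particular study's raw data.

## The gaussian model: PGLS with Pagel's lambda

For a continuous outcome \(y\) over \(n\) species, the model is

\[ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\big(0,\; \sigma^2 V(\lambda)\big), \qquad
   V(\lambda) = \lambda C + (1-\lambda)\,\mathrm{diag}(C), \]

where \(C\) is the Brownian-motion expected covariance from the tree
(\(C_{ij}\) = shared root-to-tip path length) and \(\lambda \in [0, 1]\)
is Pagel's scaling of the off-diagonal covariance: \(\lambda = 0\) is
ordinary least squares, \(\lambda = 1\) the full Brownian expectation.

Numerical choices:

* GLS solves go through a Cholesky factorization of \(V\) (or, in the
  profile, a single eigendecomposition of the correlation-scaled \(C\),
  after which every \(\lambda\) evaluation is a weighted least squares);
  \(V\) is never inverted explicitly, and the log-determinant comes from
  the factor diagonals.
* \(\lambda\) is estimated by maximizing the ML (not REML) profile
  likelihood with \(\beta, \sigma^2\) profiled out analytically, using
  bounded 1-D optimization from starts 0.1, 0.5, 0.9 with the interval
  ends also evaluated; ties are broken toward the smaller \(\lambda\).
* On a star phylogeny the profile is flat; the fit is flagged
  `lambda_unidentifiable`, reported at \(\lambda = 0\), and equals OLS.
* Wald t statistics use \(n - p\) degrees of freedom and condition on the
  estimated \(\lambda\) (the convention of the standard comparative
  toolchain); `sigma2_hat` uses the unbiased \(n-p\) divisor while the
  reported log-likelihood is the ML optimum.
* Missing data: listwise deletion per model; the tree is pruned to the
  retained species *before* the covariance is built. Pruning preserves
  the dropped stem to the original root as a root edge, so subsetting a
  covariance and re-deriving it from the pruned tree agree exactly.

## The binomial model: penalized phylogenetic logistic regression

Prevalence outcomes are per-species counts: \(y_i\) affected of \(m_i\)
surveyed. The generative view is a latent liability on the logit scale
with tree-structured correlation:

\[ \mathrm{logit}\, p_i = x_i^\top\beta + b_i, \qquad
   b \sim \mathcal{N}\big(0, \sigma_b^2 R(g)\big), \qquad
   R(g) = g\,\mathrm{cov2cor}(C) + (1-g) I, \]

with \(g = e^{-\alpha}\); \(\alpha \ge 0\) is the phylogenetic-signal
parameter (larger = weaker signal). Estimation is Firth-penalized
iteratively reweighted least squares — the penalty keeps estimates finite
and nearly unbiased at the small species counts typical of comparative
welfare data — with a working covariance on the adjusted working response
chosen to match what the data can identify:

* **Counts (\(m_i > 1\))**: the latent term both correlates species and
  overdisperses the counts with a variance floor that does not shrink
  with survey size, so the working covariance is the penalized
  quasi-likelihood form \(\sigma_b^2 R(g) + \mathrm{diag}(1/w_i)\),
  \(w_i = m_i p_i (1 - p_i)\). \((\sigma_b^2, g)\) maximize a Gaussian
  pseudo-likelihood of the working residuals with an REML correction for
  the estimated coefficients (without it the latent variance is biased
  low and Wald tests run anticonservative), searched on a log/probability
  grid and refined by Nelder–Mead.
* **Binary outcomes (\(m_i \equiv 1\))**: a Bernoulli cannot be
  overdispersed, so the correlation-only form
  \(W^{-1/2} R(g) W^{-1/2}\) is used and only \(g\) is profiled (grid
  plus 1-D refinement). On a star tree \(\mathrm{cov2cor}(C) = I\), and
  the fit reduces *exactly* to Firth-penalized ordinary logistic
  regression for every \(g\).

Wald z statistics use the model-based covariance
\((X^\top M^{-1} X)^{-1}\) and a standard-normal reference. Complete
separation is detected per predictor and refused by name; all-zero and
all-one outcomes are errors. When residuals carry no phylogenetic
correlation, \(g = 0\) and \(\alpha\) is reported at its cap
\(-\log(10^{-12})\).

In null-calibration simulations (100 species, survey sizes 5–50, latent
SD 1, full Brownian signal) the gaussian test rejects at ~0.05 and the
binomial test at ~0.07 at nominal 0.05: the binomial test pays a small
calibration price for estimating two variance parameters; this is its
honest operating characteristic and is measured, not assumed, in the
test suite.

## Partial R²

Reported effect sizes are \(t^2 / (t^2 + \mathrm{df})\), the variance in
the outcome uniquely attributable to the term; for OLS this is exactly
the squared partial correlation (verified against a residualization
oracle). Tree-block summaries apply it to the *median* Wald statistic
over the block with its degrees of freedom.

## Trees, consensus, and the tree block

Newick I/O wraps the standard tree toolchain with the contracts the
pipeline needs: branch lengths mandatory (no silent defaults), parse
errors name a character position, support labels discarded, quoted labels
resolved, spaces/underscores in taxon names unified. The consensus of a
tree block is majority-rule (a clade is kept when present in strictly
more than half of the trees — configurable via `consensus.p`), with each
retained edge's length the mean over the trees containing that edge; the
software the convention mirrors offers several consensus variants, and
this choice is stated in the configuration rather than hidden.

Phylogenetic uncertainty is propagated by refitting every model on every
tree of the block (\(\lambda\) or \((\sigma_b^2, g)\) re-estimated per
tree), then summarizing per term: median coefficient, 2.5%/97.5%
percentile interval (linear interpolation, R quantile type 7), median
Wald statistic, and partial R² from that median. Single-tree failures are
recorded and excluded; more than 5% failures aborts the run.

**What the percentile interval is and is not.** It quantifies the
sensitivity of the estimate to which phylogeny is used — the question the
tree block exists to answer. It is *not* a confidence interval for the
coefficient: it omits sampling error, and in simulation its width
(~0.04 under 10% branch-length jitter, 50 species) is several times
smaller than the sampling standard error (~0.14), so it should never be
read as parameter uncertainty. The Wald interval from any single fit
carries the sampling uncertainty; simulations show it covers at its
nominal 95% under the model.

## Leave-one-out influence

Each species is removed in turn and the model refit (all signal
parameters re-estimated). The standardized difference of species \(i\) is
the change in the focal slope divided by the SD of the leave-one-out
slope distribution; \(|\cdot| > 2\) (configurable) flags the species.
Intercept tracking is exposed alongside (`sdiff_intercept`), and the
per-deletion p-values are recorded. Two operating characteristics are
worth knowing, both consequences of the statistic itself rather than of
the implementation. First, leave-one-out slope influence behaves like a
leverage-by-residual product, whose standardized exceedance beyond 2 SD
is ~6%, not the ~4.6% a normal reference would suggest — so with 50
species about 3 flags are expected even from perfectly homogeneous data.
Second, an aberrant species at low leverage (predictor value near the
mean) cannot move the slope, however large its displacement; it moves the
intercept instead, which is why the intercept hook exists. With zero
spread in the leave-one-out estimates all standardized differences are
defined as zero.

## Screening and the hypothesis battery

Confound screening regresses each captive-population characteristic on
each predictor (PGLS for continuous characteristics, phylogenetic
logistic for binary ones, \(\alpha = 0.05\)); screened-in characteristics
join that predictor's SB models. Collinearity screening runs pairwise
phylogenetic regressions among predictors and adds flagged partners as
covariates. Battery assembly enforces the mandated controls — body mass
with brain volume (allometry), research effort with innovation counts,
natural fecundity in all hatch-rate models — and refuses, by name, any
cell violating them. The population-size predictor pairs only with the
hatch-rate outcome. No multiple-testing correction is applied across
cells (each cell is reported at per-model \(\alpha = 0.05\)); this is
deliberate and should be kept in mind when reading wide batteries.

Prevalence outcomes are analysed by PGLS on the proportion scale by
default, with `outcome.transform: none|logit|arcsine` and a binomial
battery path (`family = "binomial"` with count columns) both available,
because the choice is genuinely open for species-level prevalence data;
survey-size weighting of the gaussian path is available behind
`model.weight_by_sample_size` and off by default, matching the
conventions of the comparative toolchain this package mirrors.

## The synthetic-data generator

`simulate_tree` produces ultrametric birth–death (default), coalescent,
or star trees, depth-normalized to 1; `simulate_treeblock` applies
mean-corrected log-normal branch-length jitter (expectation-1
multipliers) and optional NNI topology moves; `simulate_traits` draws
predictors as Brownian motions, gaussian outcomes with
\(\lambda\)-structured residuals, and binomial outcomes through the
latent-liability model above; `simulate_study` assembles a full
study-shaped table (diet composition via a softmax over Brownian latents,
allometric brain volume, skewed controls, survey sizes, pair counts).

Defaults are fixed to the conditions of the study system the package
emulates: 50 species with 5–50 individuals surveyed per species (~1400
total) for the SB arm; 115 species with pairs log-uniform on 1–500 for
the breeding arm; baseline prevalences near 20%; latent logit-scale SD 1
(species prevalences mostly 3–65%); full Brownian signal; 1000-tree
blocks. Test and validation runs scale the block and replicate counts
down (stated per test) — e.g. 25-tree blocks and 100-replicate batteries —
which changes Monte-Carlo precision, not the data-generating conditions.

What the generator does *not* emulate: survey non-response and reporting
biases, measurement error in wild-trait values, correlated missingness,
non-Brownian trait evolution (OU pull, rate shifts), and topology
uncertainty beyond NNI jitter. Passing tests therefore demonstrate
correctness of the inference machinery under its own assumptions, not
robustness of any biological conclusion to violations of them.

## Known limitations

* The binomial Wald test runs mildly hot (~0.07 at nominal 0.05 at
  n = 100) because two variance parameters are estimated; a
  Kenward–Roger-style correction would be the natural refinement.
* Tree-block percentile intervals understate total uncertainty by
  construction (see above); combine them with the per-fit Wald interval.
* Influence flags inherit the heavy tails of leverage-by-residual
  products; expect ~6% of species flagged under homogeneity, and use the
  intercept hook for low-leverage aberrations.
* Ordinal predictors (IUCN rank, diet/habitat breadth) are entered
  linearly, as in the toolchain the package mirrors.
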