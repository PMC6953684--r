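---
title: "Null-model co-occurrence analysis along a stress gradient: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model co-occurrence analysis along a stress gradient: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullcooc)
```

## The scientific problem

Gall-inducing insects are sessile, host-specific herbivores: once a larva
induces a gall on a leaflet, it cannot move. If females avoid ovipositing on
leaflets already occupied by other gall morphospecies — interference
competition for oviposition sites — the community should show a *segregated*
distribution across leaflets: species pairs co-occurring on the same leaflet
less often than chance would predict. The hypothesis of interest is that such
competition matters mainly in stressful (xeric) habitats, where gallers are
abundant and leaflets small, and not in mesic habitats where natural enemies
keep densities down.

`nullcooc` implements the statistical machinery for testing this: the
C-score co-occurrence statistic, a margin-preserving randomization test, the
effect sizes used to compare sites, and the regression stages that relate
the per-site effect size to indicators of environmental stress. A
synthetic-data generator with known segregation strength makes every stage
testable without field data.

## The C-score and the fixed-fixed null model

The data for one site are a binary matrix with gall morphospecies as rows
and individual leaflets as columns; `x_ij = 1` when species `i` occurs on
leaflet `j`. For a species pair with occurrence totals `r_i`, `r_j` sharing
`S` leaflets, the number of checkerboard units is

    CU = (r_i - S)(r_j - S),

the count of leaflet pairs on which the two species form a mutually
exclusive 2x2 "checkerboard". The C-score is the mean CU over all
`R(R-1)/2` species pairs; larger values mean a more segregated community.

Observed C-scores are compared against a *fixed-fixed* null model: the
uniform distribution over all binary matrices sharing both the row totals
(species prevalences) and the column totals (species per leaflet) of the
observed matrix. Fixing both margins removes the two dominant nuisance
gradients — some species are common, some leaflets crowded — and asks only
whether the *arrangement* of co-occurrences is unusual.

`generate_null_ensemble()` samples this distribution with a sequential-swap
Markov chain: each step draws a random pair of rows and a random pair of
columns and, if the 2x2 submatrix is a checkerboard, flips it (otherwise
nothing happens). Both `burn_in` and `thin` count *attempted* swaps. This is
a deliberate choice: counting attempts makes every step a symmetric proposal
with self-loops, so the chain's stationary distribution is exactly uniform
over the fixed-margin set. Each attempt is additionally lazy with
probability 1/2 — a self-loop regardless of the draw — which makes the
chain aperiodic even in the corner case where every proposal would be
accepted (a lone 2x2 checkerboard alternates deterministically without
laziness). (The variant that counts only accepted swaps —
i.e. "move to a random neighbouring matrix" — is known to oversample
matrices with few checkerboards; with attempt-counting the two published
variants, sequential swap and trial swap, coincide, which is why the package
exposes a single algorithm.) The chain is implemented in C++ with
incremental updates of the pairwise sharing counts, and every thinned sample
is audited against the source margins.

Defaults follow common practice for matrices of this study's size (up to
~25 species x 137 leaflets): 5,000 null matrices, 30,000 attempted swaps of
burn-in, and a thinning interval of `max(1000, 10 * R * C)` attempts.
Thinning affects only the serial correlation of the ensemble, not its
marginal distribution; smaller intervals remain valid but less efficient per
sample.

For small matrices, `enumerate_fixed_margin_matrices()` constructs the
entire fixed-margin set by column-wise backtracking with feasibility
pruning, and `exact_null_distribution()` evaluates the statistic on each
member. This exhaustive oracle is independent of the chain and is used in
the test suite to verify that the sampler's distribution over matrices is
uniform (chi-square goodness of fit and total-variation distance).

## Inference per site

With observed statistic `t_obs` and null values `t_1 ... t_n`:

* `p_ge = (1 + #{t_k >= t_obs}) / (n + 1)` and
  `p_le = (1 + #{t_k <= t_obs}) / (n + 1)`. Both one-tailed probabilities
  are reported side by side (segregation reads from `p_ge`); ties count in
  both tails and the observed value is included in the reference set, so
  p-values are never 0 and `p_ge + p_le >= 1`. No doubling correction is
  applied; the two tails are reported as such. At `n = 5000` the `+1/(n+1)`
  correction is below display precision (1/5001 vs 1/5000 both print as
  .0002).
* `NES = (t_obs - mean(t)) / mean(t)` — the normalized effect size used to
  compare sites along the gradient — and the classical
  `SES = (t_obs - mean(t)) / sd(t)` are both always computed; NES is the
  default response in the gradient regressions, SES is carried because the
  standardized-effect-size literature the NES definition descends from uses
  it, and having both resolves the ambiguity without guessing.
* A matrix whose margins admit no alternative arrangement (no swap accepted
  during burn-in) is flagged *degenerate* and reported with `p = 1`,
  `NES = SES = 0` and a warning, so multi-site runs survive untestable
  sites.

`analyze_sites()` derives each site's random stream from the master seed
plus a stable hash of the site id, so per-site results are independent of
execution order.

## Stress indicators and regression stages

* **Aridity index.** `AI = P/PET` is a monthly ratio; `aridity_index()`
  averages the 24 monthly ratios (the 24 months of vegetative investment
  preceding sampling). The alternative aggregation `sum(P)/sum(PET)` is
  exposed as an option; the monthly mean is the default because the index
  is defined monthly. Lower AI = more arid.
* **Specific leaf mass.** Dry mass of a 0.38 cm² leaf disk divided by its
  area (mg/cm²); the sclerophylly proxy.
* **Soil PCA.** Correlation-matrix PCA of the 11 per-site soil variables
  (pH, H+Al, Al³⁺, Ca, Mg, P, K, SB, t, m, V). PC1 is oriented so base
  saturation (V) loads positively, making it a fertility axis. Note the
  consequence for regression signs below.
* **Gradient regressions.** `fit_stress_models()` fits Gaussian GLMs of the
  per-site NES on each indicator separately and reports a deviance-analysis
  F test. These are site-level fits (one NES, one indicator value per site;
  n = 7 in the emulated design) — plant-level replication would pseudo-
  replicate the NES, and site-level residual df are what make the reported
  F ratios interpretable.
* **Diversity models.** `fit_diversity_models()` fits Poisson GLMs of
  per-plant gall richness and abundance on site identity, switching to
  quasi-Poisson when the Pearson dispersion exceeds 1.5 ("as necessary"
  needs a threshold; 1.5 is a conventional cutoff for visible
  overdispersion). The deviance analysis uses the likelihood-ratio
  chi-square under plain Poisson and the F test once the dispersion is
  estimated.
* **Trait mixed model.** `fit_trait_mixed_model()` fits a Poisson GLMM
  (lme4) of richness/abundance on per-plant sfm with a random site
  intercept, tested against the intercept-only null by likelihood-ratio
  chi-square. The package's contribution here is the pipeline stage and its
  tests; maximum-likelihood fitting is delegated to `lme4::glmer()`.

### A note on the soil-PC1 sign

With the fertile-positive PC1 orientation, sites at the stressed end of the
gradient (poor, acidic soils) score *low* on PC1 while their communities are
the segregated, high-NES ones. The NES-PC1 regression slope is therefore
*negative* under the planted study structure, just as the NES-aridity slope
is negative (stressed sites are arid) and the NES-sfm slope positive
(stressed plants are sclerophyllous). Any statement that "soil quality is
positively related to segregation" is incompatible with that same study
structure unless the soil axis is flipped to a soil-*stress* orientation;
this package keeps the fertility orientation and the negative slope.

## The synthetic-data generator

`simulate_gall_community()` draws each leaflet's species set independently
from a pairwise-interaction (Gibbs / Markov-random-field) model

    P(x) ∝ exp( Σ_s α_s x_s  −  θ Σ_{s<t} w_s w_t x_s x_t ),

conditioned on at least one species per leaflet (the field design samples
only galled leaflets), with pair weights `w_s = q_s / mean(q)` proportional
to the species' target occupancies `q_s` (drawn log-uniformly on
[0.05, 0.4] by default, mimicking the skewed prevalence of gall
morphospecies). The per-species fields `α_s` are calibrated by fixed-point
iteration on the exactly-enumerated subset distribution (≤ 20 species) so
the realized marginal occupancies match `q` for any `θ`.

Two structural choices deserve explanation:

* **Why a Gibbs model at all:** at `θ = 0` the model is a product measure
  times a nonempty-leaflet indicator, so conditional on the realized row
  and column totals every matrix with those margins is equally likely —
  `θ = 0` is an *exact* null for the fixed-fixed test, giving the type-I
  calibration checks a true nominal target rather than an approximate one.
  Adding per-species fields (the calibration) preserves this exactly.
* **Why the pair weights are heterogeneous:** under any *uniform* pairwise
  penalty the per-leaflet energy `θ·k(k−1)/2` depends on the data only
  through the leaflet's species count `k`. The margins are then sufficient
  for the whole interaction, conditioning on them removes every trace of
  `θ`, and the fixed-fixed test provably retains its nominal level for all
  `θ` — zero power. (We verified this numerically as well: at θ = 1.5 the
  pipeline rejects at the chance rate under uniform weights.) Making
  competition strongest among the commonest morphospecies — plausible, as
  interference scales with how often each contender is present — breaks
  that sufficiency: segregation moves sharing away from abundant,
  high-margin pairs, which the C-score detects at first order. At θ = 1.5
  with 12 species and 137 leaflets the pipeline detects segregation with
  high power.

`simulate_site_environment()` plants the study's observed directions:
aridity index decreasing in the site's stress level, fertility variables
decreasing and acidity variables increasing, and per-plant sfm increasing
(means 6 → 12 mg/cm² across the gradient; AI 1.3 → 0.4; Gaussian noise
scaled per variable, with a `noise = 0` switch that makes the planted
monotonicities exact for construction checks).

`simulate_gradient_study()` assembles the full design: 7 sites with stress
levels evenly spaced on [0, 1]; `θ = theta_max` at the three sites with
stress above 0.5 and `θ = 0` below (the xeric/mesic step); species
occupancy shifted upward with stress (+0.9 on the logit scale end to end)
so richness and abundance per plant increase toward the xeric end;
per-occurrence gall counts `1 + Poisson(0.5 + 1.5·stress)` supply
abundance. Plant-level records are derived by partitioning each site's
leaflets evenly among 15 plants, keeping the community matrix and the
diversity regressions consistent.

### What the generator does and does not emulate

It reproduces the *statistical* structure the analysis assumes: binary
species-by-leaflet matrices with every leaflet galled, skewed occupancies, a
tunable pairwise association with an exact independence case, and
environmental covariates with the study's monotone stress relations. It does
not attempt mechanistic phenology, parasitoid dynamics, plant architecture,
or spatial structure among leaflets; leaflets are exchangeable given the
site. Gall *counts* are simulated independently of the binary matrix beyond
sharing its occurrences. Passing tests therefore demonstrate that the
pipeline recovers planted statistical structure, not that the field system
satisfies the model.

### A limitation of fixed-margin testing worth knowing

Conditional on both margins, the total pairwise sharing `Σ_st S_st` is a
function of the column totals alone and is therefore *conserved* across the
null set. "Aggregation" in the Gibbs sense (θ < 0) consequently cannot
depress sharing overall; it concentrates sharing on particular pairs, and
any i.i.d. compositional tilt — either sign of θ — creates repeated pair
preferences that *inflate* the variance of sharing, pushing the C-score up.
Empirically, θ < 0 yields NES scattered around zero to slightly positive
rather than reliably negative. The package's tests assert the attainable,
directional property — median NES nondecreasing in θ over θ ≥ 0 and
strongly positive under planted segregation — and we caution users against
reading a low C-score under a fixed-fixed null as evidence of aggregation
without a generator-based power analysis of their own design.

## Numerical choices and degenerate inputs

* Statistic values are exact small-integer ratios; observed and null values
  go through identical arithmetic, so tie comparison is exact.
* The sample standard deviation uses denominator `n − 1`; `sd = 0`
  (constant ensembles) yields `SES = NA` with NES still defined;
  `mean = 0` makes NES an error.
* The enumeration oracle refuses instances beyond 10⁶ partial states and
  points to the sampler.
* Loaders auto-detect comma/tab/semicolon delimiters, validate 0/1 cells
  naming the offending row and column, and reject duplicated labels.
  Subsampling to the standard 137 leaflets preserves original column order
  (determinism of downstream seeded analyses), and species absent from the
  analyzed leaflet set are dropped (with a log message) before
  co-occurrence analysis, since a pair with `r_i = 0` contributes only a
  degenerate `CU = 0`.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script rerun the whole pipeline at the
sizes that make each property informative while keeping a laptop-scale run:
5,000-matrix ensembles for margin conservation (12 x 137); 50,000 samples
per margin set for sampler-vs-oracle uniformity; 500 null communities
(10 x 50, 499 nulls each) for type-I calibration; 100 replicates at
θ = 1.5 (12 x 137, 999 nulls) plus 50 per θ on the {0, 0.5, 1.0} grid for
power and monotonicity; and 100 simulated 7-site gradient studies (299
nulls per site) for the sign-recovery rate of the three stress regressions.

## A worked example

```{r example, eval = FALSE}
study <- simulate_gradient_study(n_sites = 7, theta_max = 1.5, seed = 99)
res <- run_gradient_pipeline(study, n_null = 999, burn_in = 30000, seed = 2)
res$cooc[, c("site_id", "null_min", "null_max", "observed", "p_ge", "p_le")]
res$stress_fits
```

The xeric sites (the three highest stress levels) come out with small
`p_ge` and positive NES; the mesic sites do not; and the three regression
slopes show the sfm-positive, aridity-negative, soilPC1-negative pattern
discussed above.
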