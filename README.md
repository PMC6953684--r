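# nullcooc

Null-model co-occurrence analysis for gall-inducing insect communities —
and, more generally, for any binary species-by-sample presence/absence
matrix — with the downstream regression stages that relate community
structure to an environmental stress gradient.

Sessile herbivores such as gall-inducing insects compete for oviposition
sites on individual leaflets. If that competition structures the community,
species pairs should *segregate*: co-occur on the same leaflet less often
than expected given how common each species is and how crowded each leaflet
is. `nullcooc` tests this with:

* the **C-score**: for each unordered species pair with occurrence totals
  `r_i`, `r_j` sharing `S` leaflets, the checkerboard units are
  `CU = (r_i − S)(r_j − S)`; the C-score is the mean CU over all
  `R(R−1)/2` pairs (higher = more segregated);
* a **fixed-fixed null model**: the uniform distribution over all binary
  matrices preserving both the observed row totals and column totals,
  sampled by a compiled sequential-swap Markov chain (attempt-counted, so
  the stationary distribution is exactly uniform), with an exhaustive
  enumeration oracle for small matrices;
* **inference per site**: both one-tailed permutation p-values with the
  `+1/(n+1)` correction, the normalized effect size
  `NES = (obs − mean)/mean` used to compare sites, and the classical
  `SES = (obs − mean)/sd`;
* **stress-gradient stages**: aridity index (mean monthly P/PET), specific
  leaf mass from 0.38 cm² leaf disks, correlation-matrix PCA of soil
  chemistry (PC1 oriented fertile-positive), Gaussian site-level
  regressions of NES on each stress indicator, Poisson/quasi-Poisson
  diversity models, and a Poisson GLMM of diversity on leaf sclerophylly;
* a **synthetic-data generator**: leaflet communities drawn from a
  pairwise-interaction model with known segregation strength θ (θ = 0 is an
  exact fixed-margin null), and full 7-site gradient studies with planted
  environmental relations, so every stage is testable without field data.

See the methods vignette (`vignettes/nullcooc-methods.Rmd`) for the model,
the design decisions and the generator's scope.

## A worked example

```r
library(nullcooc)

m <- pa_matrix(rbind(A = c(1, 1, 0, 0),
                     B = c(0, 0, 1, 1),
                     C = c(1, 0, 1, 0)))
c_score(m)
#> [1] 2

# a synthetic segregated community, analyzed end to end
sim <- simulate_gall_community(12, 137, theta = 1.5, seed = 3)
analyze_site(drop_empty_species(sim), n_null = 4999, burn_in = 30000,
             seed = 5)
#> cooc_result [synthetic]: observed C-score 285.773, null 281.197 (sd 0.974, range 278.015-285.288)
#>   p(obs >= exp) = 0.0002, p(obs <= exp) = 1, NES = 0.0163, SES = 4.697
```

The observed C-score sits above all 4,999 margin-preserving null matrices
(`p_ge = 0.0002`, the smallest attainable value at this ensemble size): the
community co-occurs less than its margins predict, i.e. it is segregated,
and `NES > 0` quantifies by how much relative to the null expectation.

A full gradient analysis on simulated data:

```r
study <- simulate_gradient_study(n_sites = 7, theta_max = 1.5, seed = 99)
res <- run_gradient_pipeline(study, n_null = 999, burn_in = 30000, seed = 2)
res$cooc[, c("site_id", "null_min", "null_max", "observed", "p_ge", "p_le")]
#>   site_id null_min null_max observed  p_ge  p_le
#> 1  site01 379.0455 396.8636 385.3636 0.698 0.306
#> 2  site02 321.2273 334.5455 323.6515 0.956 0.046
#> 3  site03 335.5909 350.3333 342.2879 0.634 0.368
#> 4  site04 662.2273 679.4242 669.1970 0.455 0.546
#> 5  site05 724.7727 739.4091 740.6818 0.001 1.000
#> 6  site06 672.8636 685.5303 695.0000 0.001 1.000
#> 7  site07 842.9545 858.7273 851.9848 0.228 0.777

res$stress_fits[, c("explanatory", "statistic", "p_value", "slope")]
#>     explanatory statistic    p_value        slope
#> 1      sfm_mean  3.499076 0.12032357  0.003189674
#> 2 aridity_index  4.518974 0.08686630 -0.025205289
#> 3      soil_pc1  4.578155 0.08535379 -0.002473063
```

Sites 05-07 carry planted segregation (stress above 0.5); two of the three
are individually flagged (`p_ge = 0.001`) in this realization, and the
regression slopes show the gradient's sign pattern — NES rising with
specific leaf mass, falling with the aridity index and with the
fertile-positive soil PC1. Single-realization p-values at n = 7 sites are
noisy by design; the acceptance script measures the sign-recovery rate
(around 99% of simulated studies) and the per-site power (around 100% at
theta = 1.5 with 999 nulls) over 100 replicates.

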