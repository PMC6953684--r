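Package: nullcooc
Title: Null-Model Co-Occurrence Analysis of Gall-Inducing Insect Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing species segregation in binary species-by-leaflet
    presence/absence matrices with the C-score checkerboard statistic and
    fixed-fixed (margin-preserving) sequential-swap null models, including
    exact enumeration oracles for small matrices, two-tailed permutation
    p-values, normalized (NES) and classical (SES) effect sizes, and the
    downstream environmental stress-gradient stages: aridity index from
    monthly precipitation and potential evapotranspiration, specific leaf
    mass, soil-fertility principal component analysis, and the diversity and
    effect-size regressions. A synthetic-data generator produces multi-site
    gradient studies with known pairwise segregation strength so every
    pipeline stage can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
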