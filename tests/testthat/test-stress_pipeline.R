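test_that("aridity index averages monthly P/PET and is homogeneous in P", {
  expect_equal(aridity_index(rep(50, 24), rep(50, 24)), 1)
  expect_equal(aridity_index(c(100, 50), c(100, 100)), 0.75)
  p <- runif(24, 10, 200)
  pet <- runif(24, 50, 150)
  expect_equal(aridity_index(2 * p, pet), 2 * aridity_index(p, pet))
  expect_equal(aridity_index(p, pet, method = "totals"), sum(p) / sum(pet))
  expect_error(aridity_index(c(10, 10), c(100, 0)), "positive")
  expect_error(aridity_index(c(10, NA, 10), c(1, 1, 1)), "positions: 2")
  expect_error(aridity_index(1:3, 1:4), "length")
})

test_that("specific leaf mass is dry mass per disk area", {
  expect_equal(specific_leaf_mass(3.8), 10)
  expect_equal(specific_leaf_mass(0), 0)
  expect_equal(specific_leaf_mass(c(1, 2), 0.5), c(2, 4))
  expect_equal(specific_leaf_mass(5 * 1.9), 5 * specific_leaf_mass(1.9))
  expect_error(specific_leaf_mass(-1), "negative")
  expect_error(specific_leaf_mass(1, 0), "positive")
})

test_that("soil PCA standardizes, orients PC1 fertile-positive and reconstructs", {
  set.seed(14)
  soil <- matrix(rnorm(7 * 11), 7, 11)
  colnames(soil) <- c("pH", "H_Al", "Al", "Ca", "Mg", "P", "K", "SB", "t",
                      "m", "V")
  rownames(soil) <- paste0("s", 1:7)
  p <- soil_pca(soil)
  expect_equal(sum(p$variance_fractions), 1)
  expect_gte(p$loadings["V", 1], 0)
  # scores x loadings' reconstructs the standardized table
  expect_equal(p$scores %*% t(p$loadings), scale(soil), ignore_attr = TRUE)

  # rank-1 case: two perfectly correlated variables, PC1 explains everything
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  p1 <- soil_pca(x)
  expect_equal(p1$variance_fractions[1], 1)

  soil[, "m"] <- 3
  expect_error(soil_pca(soil), "constant soil variable.*m")
  expect_error(soil_pca(matrix(rnorm(4), 2, 2)), "at least 3 sites")
})

test_that("gaussian stress regressions recover a perfectly linear response", {
  sfm <- c(5, 6, 7, 8, 9, 10, 11)
  tab <- data.frame(site_id = paste0("s", 1:7), nes = 0.01 * sfm - 0.03,
                    sfm_mean = sfm)
  fit <- fit_stress_models(tab)
  expect_equal(fit$slope, 0.01, tolerance = 1e-8)
  expect_lt(fit$residual_deviance, 1e-12)
  expect_equal(fit$df, 5) # n - 2 residual df at 7 sites

  tab$sfm_mean <- 5
  expect_error(fit_stress_models(tab), "constant across sites")
  expect_error(fit_stress_models(tab[1:2, ]), "at least 3 sites")
})

test_that("stress regressions report deviance analysis per indicator", {
  set.seed(16)
  tab <- data.frame(
    site_id = paste0("s", 1:7),
    nes = rnorm(7, 0.01), sfm_mean = rnorm(7, 8),
    aridity_index = runif(7, 0.4, 1.3), soil_pc1 = rnorm(7)
  )
  fit <- fit_stress_models(tab)
  expect_equal(fit$explanatory, c("sfm_mean", "aridity_index", "soil_pc1"))
  expect_true(all(fit$residual_deviance >= 0))
  expect_true(all(fit$p_value >= 0 & fit$p_value <= 1))
})

test_that("diversity models detect a planted site effect and dispersion", {
  set.seed(18)
  n_rep <- 20
  detected <- vapply(seq_len(n_rep), function(i) {
    galls <- data.frame(
      plant_id = paste0("p", 1:30),
      site_id = rep(c("mesic", "xeric"), each = 15),
      richness = c(rpois(15, 2), rpois(15, 4)), # 2x richness in xeric
      abundance = c(rpois(15, 5), rpois(15, 10))
    )
    fit <- fit_diversity_models(galls)
    all(fit$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(detected), 0.9)

  # overdispersed counts trigger the quasi-Poisson correction
  set.seed(20)
  galls <- data.frame(
    plant_id = paste0("p", 1:40),
    site_id = rep(c("a", "b"), each = 20),
    richness = rnbinom(40, mu = 5, size = 0.8),
    abundance = rnbinom(40, mu = 20, size = 0.8)
  )
  galls$richness[1] <- galls$richness[1] + 1 # guard against all-zero draws
  fit <- fit_diversity_models(galls)
  expect_true(all(fit$dispersion > 1.5))
  expect_true(all(fit$family == "quasipoisson"))

  expect_error(fit_diversity_models(galls[galls$site_id == "a", ]),
               "at least 2 sites")
  galls$richness <- 0
  expect_error(fit_diversity_models(galls, responses = "richness"),
               "all-zero")
})

test_that("identical sites give a roughly uniform site-effect p-value", {
  set.seed(22)
  pvals <- vapply(1:40, function(i) {
    galls <- data.frame(
      plant_id = paste0("p", 1:30),
      site_id = rep(c("a", "b"), each = 15),
      richness = rpois(30, 3),
      abundance = rpois(30, 8)
    )
    fit_diversity_models(galls, responses = "richness")$p_value
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0)   # not everything significant ...
  expect_lt(mean(pvals < 0.05), 0.2) # ... and close to the nominal rate
})

test_that("trait mixed model tests sfm by likelihood ratio against the null", {
  set.seed(24)
  sites <- rep(paste0("s", 1:5), each = 15)
  site_int <- rep(rnorm(5, 0, 0.2), each = 15)
  sfm <- rnorm(75, 8, 1.5)
  strong <- data.frame(
    plant_id = paste0("p", 1:75), site_id = sites, sfm = sfm,
    richness = rpois(75, exp(0.2 + site_int + 0.25 * (sfm - 8)))
  )
  fit <- fit_trait_mixed_model(strong)
  expect_gte(fit$chisq, 0)
  expect_lt(fit$p_value, 0.05)
  expect_gt(fit$slope, 0)

  null_data <- strong
  null_data$richness <- rpois(75, exp(0.5 + site_int))
  fit0 <- fit_trait_mixed_model(null_data)
  expect_gte(fit0$chisq, 0)

  expect_error(fit_trait_mixed_model(strong[strong$site_id == "s1", ]),
               "single site")
  expect_error(fit_trait_mixed_model(strong[, c("plant_id", "site_id",
                                                "richness")]),
               "sfm")
})
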