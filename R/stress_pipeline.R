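#' Aridity index from monthly climate series
#'
#' `AI = P / PET` per month, aggregated over the series (the two years of
#' vegetative investment preceding sampling in the study design). Lower
#' values indicate a more arid, water-deprived habitat.
#'
#' @param precip monthly precipitation totals (mm).
#' @param pet monthly potential evapotranspiration (mm); must be positive.
#' @param method `"monthly_mean"` (default): mean of the monthly P/PET
#'   ratios, preserving the monthly form of the index; `"totals"`:
#'   `sum(P)/sum(PET)`.
#' @return The aridity index (dimensionless, > 0 whenever some rain fell).
#' @examples
#' aridity_index(c(100, 50), c(100, 100)) # 0.75
#' @export
aridity_index <- function(precip, pet, method = c("monthly_mean", "totals")) {
  method <- match.arg(method)
  if (length(precip) != length(pet)) {
    stop("precipitation and PET series differ in length")
  }
  gaps <- which(is.na(precip) | is.na(pet))
  if (length(gaps) > 0) {
    stop("missing monthly values at positions: ", paste(gaps, collapse = ", "))
  }
  if (any(pet <= 0)) {
    stop("PET must be positive every month (non-positive at: ",
         paste(which(pet <= 0), collapse = ", "), ")")
  }
  if (any(precip < 0)) stop("negative precipitation")
  switch(method,
         monthly_mean = mean(precip / pet),
         totals = sum(precip) / sum(pet))
}

#' Specific leaf mass from a leaf-disk measurement
#'
#' Dry mass of a leaf disk divided by its area; the study punches a 0.38 cm2
#' disk per leaflet, so sfm is in mg/cm2. Higher values indicate more
#' sclerophyllous leaves.
#'
#' @param disk_dry_mass dry mass (mg); vectorized.
#' @param disk_area disk area (cm2), default 0.38.
#' @return sfm in mg/cm2.
#' @examples
#' specific_leaf_mass(3.8) # 10
#' @export
specific_leaf_mass <- function(disk_dry_mass, disk_area = 0.38) {
  if (any(disk_area <= 0)) stop("disk area must be positive")
  if (any(disk_dry_mass < 0)) stop("negative dry mass")
  disk_dry_mass / disk_area
}

#' Principal component analysis of site soil chemistry
#'
#' Correlation-matrix PCA (variables standardized to zero mean, unit
#' variance) of the per-site soil fertility table. The first axis is oriented
#' so that base saturation (`V`) loads positively, making PC1 a fertility
#' gradient: fertile sites score high, poor acidic sites low.
#'
#' @param soil data frame or matrix of sites x soil variables (e.g. pH,
#'   H_Al, Al, Ca, Mg, P, K, SB, t, m, V); rownames are site ids.
#' @return A list: `scores` (sites x PCs), `loadings` (variables x PCs),
#'   `variance_fractions` (per axis, summing to 1), `sdev`.
#' @export
soil_pca <- function(soil) {
  x <- as.matrix(soil)
  if (nrow(x) < 3) stop("soil PCA needs at least 3 sites")
  if (anyNA(x)) stop("soil table contains missing values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant soil variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- p$x
  loadings <- p$rotation
  vcol <- grep("^V$", colnames(x), ignore.case = TRUE)
  if (length(vcol) == 1 && loadings[vcol, 1] < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  list(scores = scores, loadings = loadings,
       variance_fractions = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
}

tidy_anodev <- function(fit, response, explanatory, test = "F") {
  an <- stats::anova(fit, test = test)
  stat_col <- if (test == "F") "F" else "Deviance"
  data.frame(
    response = response,
    explanatory = explanatory,
    family = fit$family$family %||% "mixed",
    deviance = an$Deviance[2],
    residual_deviance = an[["Resid. Dev"]][nrow(an)],
    df = an[["Resid. Df"]][nrow(an)],
    statistic = if (test == "F") an$F[2] else an$Deviance[2],
    p_value = an[[grep("^Pr", names(an), value = TRUE)[1]]][2],
    row.names = NULL
  )
}

#' Gradient regressions of the co-occurrence effect size on stress indicators
#'
#' Gaussian GLMs (ordinary least squares) of the per-site NES C-score on each
#' stress indicator separately — mean specific leaf mass, aridity index and
#' soil PC1 — followed by deviance analysis with an F test. Site-level
#' design: one NES and one indicator value per site.
#'
#' @param site_table data frame with one row per site and columns `nes`,
#'   `sfm_mean`, `aridity_index`, `soil_pc1` (missing indicator columns are
#'   skipped).
#' @return A data frame with one row per fitted model: response, explanatory,
#'   deviance, residual deviance, residual df, F, p, `slope`.
#' @export
fit_stress_models <- function(site_table) {
  if (nrow(site_table) < 3) stop("need at least 3 sites to fit a slope")
  indicators <- intersect(c("sfm_mean", "aridity_index", "soil_pc1"),
                          colnames(site_table))
  if (length(indicators) == 0) stop("no stress indicator columns found")
  rows <- lapply(indicators, function(v) {
    x <- site_table[[v]]
    if (stats::sd(x) == 0) {
      stop("indicator '", v, "' is constant across sites: slope undefined")
    }
    fit <- stats::glm(stats::reformulate(v, "nes"), data = site_table,
                      family = stats::gaussian())
    out <- tidy_anodev(fit, "nes", v, test = "F")
    out$slope <- stats::coef(fit)[[v]]
    out
  })
  do.call(rbind, rows)
}

pearson_dispersion <- function(fit) {
  sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
}

#' Among-site diversity models for gall richness and abundance
#'
#' Poisson log-linear GLM of per-plant gall richness (and abundance) on site
#' identity, followed by deviance analysis (likelihood-ratio chi-square
#' under Poisson; F once the dispersion is estimated). When the Pearson
#' dispersion exceeds `dispersion_threshold` the model is refit as
#' quasi-Poisson.
#'
#' @param galls data frame with columns `plant_id`, `site_id`, `richness`,
#'   `abundance`.
#' @param responses which responses to model.
#' @param dispersion_threshold refit as quasi-Poisson above this Pearson
#'   dispersion (default 1.5).
#' @return A data frame (one row per response) as in [fit_stress_models()],
#'   plus `dispersion`.
#' @export
fit_diversity_models <- function(galls,
                                 responses = c("richness", "abundance"),
                                 dispersion_threshold = 1.5) {
  galls$site_id <- factor(galls$site_id)
  if (nlevels(galls$site_id) < 2) stop("need at least 2 sites")
  if (any(table(galls$site_id) < 2)) stop("need at least 2 plants per site")
  rows <- lapply(responses, function(resp) {
    y <- galls[[resp]]
    if (all(y == 0)) stop("all-zero response: ", resp)
    fit <- stats::glm(stats::reformulate("site_id", resp), data = galls,
                      family = stats::poisson())
    disp <- pearson_dispersion(fit)
    if (disp > dispersion_threshold) {
      fit <- stats::glm(stats::reformulate("site_id", resp), data = galls,
                        family = stats::quasipoisson())
    }
    # chi-square deviance test under Poisson (dispersion fixed at 1);
    # F test once the dispersion is estimated (quasi-Poisson)
    out <- tidy_anodev(fit, resp, "site_id",
                       test = if (disp > dispersion_threshold) "F" else
                         "Chisq")
    out$dispersion <- disp
    out
  })
  do.call(rbind, rows)
}

#' Mixed-effects model of gall diversity on leaf sclerophylly
#'
#' Poisson generalized linear mixed model (random site intercept) of
#' per-plant gall richness (or abundance) on the plant's specific leaf mass,
#' compared to the intercept-only null (same random effect) by a
#' likelihood-ratio chi-square test.
#'
#' @param galls data frame with columns `plant_id`, `site_id`, the response,
#'   and `sfm` (per-plant specific leaf mass, mg/cm2).
#' @param response `"richness"` (default) or `"abundance"`.
#' @return A data frame row: response, explanatory, slope (on the log link),
#'   `chisq` (LR statistic, always >= 0), `df`, `p_value`, plus the fitted
#'   models in attribute `"fits"`.
#' @export
fit_trait_mixed_model <- function(galls, response = "richness") {
  galls$site_id <- factor(galls$site_id)
  if (nlevels(galls$site_id) < 2) {
    stop("random site effect unidentifiable with a single site")
  }
  if (is.null(galls$sfm)) stop("column 'sfm' (per-plant sfm) is required")
  full <- lme4::glmer(
    stats::as.formula(paste(response, "~ sfm + (1 | site_id)")),
    data = galls, family = stats::poisson()
  )
  null <- lme4::glmer(
    stats::as.formula(paste(response, "~ 1 + (1 | site_id)")),
    data = galls, family = stats::poisson()
  )
  lr <- stats::anova(null, full)
  out <- data.frame(
    response = response, explanatory = "sfm",
    slope = lme4::fixef(full)[["sfm"]],
    chisq = max(0, lr$Chisq[2]),
    df = lr$Df[2],
    p_value = lr[["Pr(>Chisq)"]][2],
    row.names = NULL
  )
  attr(out, "fits") <- list(full = full, null = null)
  out
}
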