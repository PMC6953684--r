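#' Per-site stress-indicator table
#'
#' Collapses site environments and leaf records to the site-level table the
#' gradient regressions consume: aridity index, mean specific leaf mass and
#' soil PC1 score per site.
#'
#' @param environments named list of `site_environment` objects (or any list
#'   with `site_id`, `monthly_precip`, `monthly_pet`, `soil_chemistry`,
#'   `leaf_disks`).
#' @return A data frame: `site_id`, `aridity_index`, `sfm_mean`, `soil_pc1`.
#' @export
gradient_site_table <- function(environments) {
  soil <- do.call(rbind, lapply(environments, function(e) e$soil_chemistry))
  rownames(soil) <- vapply(environments, function(e) e$site_id, character(1))
  pca <- soil_pca(soil)
  data.frame(
    site_id = rownames(soil),
    aridity_index = vapply(environments, function(e) {
      aridity_index(e$monthly_precip, e$monthly_pet)
    }, numeric(1)),
    sfm_mean = vapply(environments, function(e) mean(e$leaf_disks$sfm),
                      numeric(1)),
    soil_pc1 = pca$scores[, 1],
    row.names = NULL
  )
}

#' Run the full gradient analysis on a (synthetic or loaded) study
#'
#' Per-site co-occurrence analysis (fixed-fixed null model, NES), the
#' site-level stress-indicator table, and the three NES-on-indicator
#' Gaussian regressions.
#'
#' @param study a `gradient_study` from [simulate_gradient_study()] (or any
#'   list with `matrices` and `environments`).
#' @param n_null,burn_in,thin null-model settings per site.
#' @param seed master seed; per-site streams derive from it.
#' @return A list: `cooc` (per-site co-occurrence results),
#'   `site_table` (indicators joined with NES), `stress_fits`
#'   (deviance-analysis table from [fit_stress_models()]).
#' @export
run_gradient_pipeline <- function(study, n_null = 5000, burn_in = 30000,
                                  thin = NULL, seed = 1L) {
  cooc <- analyze_sites(study$matrices, n_null = n_null, burn_in = burn_in,
                        thin = thin, seed = seed)
  site_table <- gradient_site_table(study$environments)
  site_table <- merge(site_table, cooc[, c("site_id", "nes", "ses", "p_ge")],
                      by = "site_id", sort = FALSE)
  list(
    cooc = cooc,
    site_table = site_table,
    stress_fits = fit_stress_models(site_table)
  )
}
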