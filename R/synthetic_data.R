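#' Simulate a gall community matrix with known segregation strength
#'
#' Each leaflet's species set `x` is drawn independently from a
#' pairwise-interaction (Gibbs) model,
#' `P(x) \propto exp(sum_s x_s logit(q_s) - theta * sum_(s<t) w_s w_t x_s x_t)`,
#' with pair weights `w_s = q_s / mean(q)`, conditioned on at least one
#' species per leaflet (every sampled leaflet is galled, as in the field
#' design). `theta > 0` penalizes co-occurrence (segregation), `theta = 0`
#' gives independent occupancy — and, conditional on the realized margins,
#' exactly the uniform fixed-margin null — and `theta < 0` rewards
#' co-occurrence (aggregation).
#'
#' The occupancy-proportional pair weights make competition strongest among
#' the commonest morphospecies (interference scales with how often each
#' contender is present). They are also what makes the interaction visible
#' to a margin-conditioned test: under any *uniform* pairwise penalty the
#' per-leaflet energy depends on the data only through the leaflet's species
#' count, so conditioning on row and column totals removes the signal
#' entirely and the fixed-fixed null retains exact nominal level for every
#' theta. Heterogeneous weights instead redistribute sharing across species
#' pairs at fixed margins, which the C-score detects.
#'
#' For up to 20 species the subset distribution is computed exactly and
#' leaflets are drawn i.i.d. from it; beyond that a rejection sampler is used
#' (available for `theta >= 0` only).
#'
#' @param n_species number of gall morphospecies (rows), >= 2.
#' @param n_leaflets number of leaflets (columns), default 137.
#' @param base_occupancy per-species marginal occurrence probability `q_s` in
#'   (0,1); a single value is recycled; `NULL` (default) draws each `q_s`
#'   log-uniformly from \[0.05, 0.4\], mimicking the skewed occupancy of gall
#'   morphospecies.
#' @param theta pairwise interaction strength (default 0).
#' @param seed optional integer seed.
#' @param site_id site label for the returned matrix.
#' @return A [pa_matrix()] with attributes `theta` and `base_occupancy`.
#' @examples
#' m <- simulate_gall_community(6, 50, theta = 1, seed = 1)
#' all(colSums(m) >= 1) # every leaflet galled
#' @export
simulate_gall_community <- function(n_species, n_leaflets = 137,
                                    base_occupancy = NULL, theta = 0,
                                    seed = NULL, site_id = "synthetic") {
  stopifnot(n_species >= 2, n_leaflets >= 1)
  with_seed(seed, {
    q <- base_occupancy
    if (is.null(q)) q <- exp(stats::runif(n_species, log(0.05), log(0.4)))
    if (length(q) == 1) q <- rep(q, n_species)
    stopifnot(length(q) == n_species, all(q > 0), all(q < 1))
    ent <- if (n_species <= 20) {
      sample_leaflets_exact(q, theta, n_leaflets)
    } else {
      sample_leaflets_rejection(q, theta, n_leaflets)
    }
    rownames(ent) <- paste0("sp", seq_len(n_species))
    colnames(ent) <- paste0("lf", seq_len(n_leaflets))
    out <- pa_matrix(ent, site_id = site_id)
    attr(out, "theta") <- theta
    attr(out, "base_occupancy") <- q
    out
  })
}

# Occupancy-proportional pair weights: competition strongest among the
# commonest morphospecies, and heterogeneous so the interaction survives
# margin conditioning.
pair_weights <- function(q) q / mean(q)

# Exact i.i.d. sampling of leaflet species sets by enumerating all non-empty
# subsets of <= 20 species (weights depend on the subset through the sum of
# per-species fields and the weighted sum over co-occurring pairs).
#
# The per-species fields are calibrated by fixed-point iteration so that the
# realized marginal occupancy of each species matches the target q even when
# theta suppresses (or rewards) co-occupancy; adding fields changes only the
# row-margin structure, so theta = 0 remains an exact uniform fixed-margin
# null after calibration.
sample_leaflets_exact <- function(q, theta, n_leaflets, calibrate = TRUE,
                                  max_iter = 25, tol = 1e-6) {
  S <- length(q)
  nsub <- 2^S
  w <- pair_weights(q)
  idx <- 0:(nsub - 1)
  hasbit <- function(s) bitwAnd(idx, bitwShiftL(1L, s - 1L)) > 0
  wsum <- numeric(nsub)  # sum of w_s over the subset
  wsq <- numeric(nsub)   # sum of w_s^2 over the subset
  for (s in seq_len(S)) {
    has <- hasbit(s)
    wsum[has] <- wsum[has] + w[s]
    wsq[has] <- wsq[has] + w[s]^2
  }
  pairsum <- (wsum^2 - wsq) / 2  # sum over s<t in subset of w_s w_t
  logit <- stats::qlogis(q)
  subset_weights <- function(logit) {
    linsum <- numeric(nsub)
    for (s in seq_len(S)) {
      has <- hasbit(s)
      linsum[has] <- linsum[has] + logit[s]
    }
    logw <- linsum - theta * pairsum
    logw[1] <- -Inf # empty set excluded: every leaflet must be galled
    exp(logw - max(logw[-1]))
  }
  wts <- subset_weights(logit)
  if (calibrate) {
    for (it in seq_len(max_iter)) {
      total <- sum(wts)
      p <- vapply(seq_len(S), function(s) sum(wts[hasbit(s)]) / total,
                  numeric(1))
      if (max(abs(p - q)) < tol) break
      logit <- logit + stats::qlogis(q) - stats::qlogis(p)
      wts <- subset_weights(logit)
    }
  }
  draw <- sample.int(nsub, n_leaflets, replace = TRUE, prob = wts)
  ent <- matrix(0L, S, n_leaflets)
  for (s in seq_len(S)) {
    ent[s, ] <- as.integer(bitwAnd(draw - 1L, bitwShiftL(1L, s - 1L)) > 0)
  }
  ent
}

# Envelope rejection from the independent-occupancy product measure; valid
# for theta >= 0 where exp(-theta * pairsum) <= 1.
sample_leaflets_rejection <- function(q, theta, n_leaflets,
                                      max_rejection = 0.999) {
  if (theta < 0) {
    stop("rejection sampler supports theta >= 0 only; ",
         "use <= 20 species for aggregation (exact sampler)")
  }
  S <- length(q)
  w <- pair_weights(q)
  ent <- matrix(0L, S, n_leaflets)
  filled <- 0L
  attempts <- 0
  while (filled < n_leaflets) {
    batch <- max(1000L, 4L * (n_leaflets - filled))
    x <- matrix(stats::rbinom(S * batch, 1L, q), nrow = S)
    kk <- colSums(x)
    wx <- crossprod(x, w)        # sum of w_s over present species
    wx2 <- crossprod(x, w^2)
    pairsum <- (wx^2 - wx2) / 2
    acc <- kk >= 1 & stats::runif(batch) < exp(-theta * pairsum)
    attempts <- attempts + batch
    hits <- which(acc)
    if (length(hits) > 0) {
      take <- hits[seq_len(min(length(hits), n_leaflets - filled))]
      ent[, filled + seq_along(take)] <- x[, take]
      filled <- filled + length(take)
    }
    if (attempts > 5000 && (filled / attempts) < (1 - max_rejection)) {
      stop("rejection rate above ", max_rejection,
           ": reduce theta or base occupancy")
    }
  }
  ent
}

#' Simulate the environment and leaf traits of one site
#'
#' Produces a 24-month climate series, the 11-variable soil chemistry vector
#' and per-plant leaf-disk records for a site at a given position on the
#' stress gradient. Planted relations (recorded in `ground_truth`): the
#' aridity index decreases with stress; fertility variables (pH, Ca, Mg, P,
#' K, SB, t, V) decrease and acidity variables (H_Al, Al, m) increase with
#' stress; per-plant specific leaf mass increases with stress (stressed
#' plants are more sclerophyllous).
#'
#' @param stress_level position on the gradient in \[0, 1\] (1 = most xeric).
#' @param seed optional integer seed.
#' @param n_plants plants sampled per site (default 15).
#' @param noise noise multiplier; 0 gives the deterministic planted means.
#' @param site_id site label.
#' @return A list of class `site_environment`: `site_id`, `stress_level`,
#'   `monthly_precip`, `monthly_pet`, `aridity_index`, `soil_chemistry`
#'   (named vector), `leaf_disks` (data frame: plant_id, site_id, disk_area,
#'   disk_dry_mass, sfm), `ground_truth`.
#' @export
simulate_site_environment <- function(stress_level, seed = NULL,
                                      n_plants = 15, noise = 1,
                                      site_id = "synthetic") {
  stopifnot(stress_level >= 0, stress_level <= 1)
  with_seed(seed, {
    months <- 1:24
    pet <- pmax(20, 90 + 30 * sin(2 * pi * months / 12) +
                  stats::rnorm(24, 0, 3 * noise))
    ai_target <- 1.3 - 0.9 * stress_level
    precip <- pmax(0, pet * (ai_target + stats::rnorm(24, 0, 0.04 * noise)))
    soil_means <- c(
      pH = 6.0 - 1.5 * stress_level,
      H_Al = 2 + 6 * stress_level,
      Al = 0.2 + 1.3 * stress_level,
      Ca = 4 - 3.2 * stress_level,
      Mg = 1.5 - 1.1 * stress_level,
      P = 10 - 8 * stress_level,
      K = 100 - 70 * stress_level,
      SB = 6 - 4.8 * stress_level,
      t = 7 - 2 * stress_level,
      m = 5 + 60 * stress_level,
      V = 70 - 55 * stress_level
    )
    soil_sd <- abs(soil_means) * 0.05 * noise
    soil <- pmax(0.01, soil_means + stats::rnorm(length(soil_means),
                                                 0, soil_sd))
    names(soil) <- names(soil_means)
    sfm_mean <- 6 + 6 * stress_level
    sfm <- pmax(0.5, stats::rnorm(n_plants, sfm_mean, 0.8 * noise))
    leaf <- data.frame(
      plant_id = paste0(site_id, "_p", seq_len(n_plants)),
      site_id = site_id,
      disk_area = 0.38,
      disk_dry_mass = sfm * 0.38,
      sfm = sfm
    )
    structure(
      list(site_id = site_id, stress_level = stress_level,
           monthly_precip = precip, monthly_pet = pet,
           aridity_index = aridity_index(precip, pet),
           soil_chemistry = soil, leaf_disks = leaf,
           ground_truth = list(
             ai_slope = -0.9, sfm_slope = 6,
             fertility_decreasing = c("pH", "Ca", "Mg", "P", "K", "SB",
                                      "t", "V"),
             acidity_increasing = c("H_Al", "Al", "m")
           )),
      class = "site_environment"
    )
  })
}

#' Simulate a full multi-site stress-gradient study
#'
#' End-to-end synthetic analogue of the field design: `n_sites` sites with
#' stress levels evenly spaced on \[0, 1\], each with a species-by-leaflet
#' matrix, a 24-month climate series, a soil chemistry vector, and per-plant
#' leaf and gall records. The pairwise segregation strength follows a step
#' design mirroring the xeric/mesic split: `theta = theta_max` at sites with
#' stress above 0.5, `theta = 0` below. Species occupancy (and hence gall
#' richness and abundance per plant) increases with stress, reproducing the
#' greater galler diversity of xeric habitats.
#'
#' Plant-level records are derived by partitioning each site's leaflets
#' evenly among the plants; per-occurrence gall counts (for abundance) are
#' drawn with a mean that increases with stress.
#'
#' @param n_sites number of sites (default 7).
#' @param theta_max segregation strength at xeric sites (default 1.5).
#' @param seed optional master integer seed.
#' @param n_species gall morphospecies per site (default 12).
#' @param n_leaflets leaflets per site (default 137).
#' @param n_plants plants per site (default 15).
#' @param noise noise multiplier for the environmental generator.
#' @return A list of class `gradient_study`: `sites` (data frame: site_id,
#'   stress_level, theta), `matrices` (named list of [pa_matrix()]),
#'   `environments` (named list of `site_environment`), `leaf_disks` and
#'   `galls` (pooled data frames), `ground_truth`.
#' @export
simulate_gradient_study <- function(n_sites = 7, theta_max = 1.5,
                                    seed = NULL, n_species = 12,
                                    n_leaflets = 137, n_plants = 15,
                                    noise = 1) {
  stopifnot(n_sites >= 2)
  with_seed(seed, {
    stress <- seq(0, 1, length.out = n_sites)
    theta <- ifelse(stress > 0.5, theta_max, 0)
    ids <- sprintf("site%02d", seq_len(n_sites))
    occupancy_shift <- 0.9 # logit-scale occupancy increase from mesic to xeric
    matrices <- list()
    environments <- list()
    galls <- list()
    for (i in seq_len(n_sites)) {
      q0 <- exp(stats::runif(n_species, log(0.05), log(0.4)))
      q <- stats::plogis(stats::qlogis(q0) + occupancy_shift * stress[i])
      m <- simulate_gall_community(n_species, n_leaflets,
                                   base_occupancy = q, theta = theta[i],
                                   site_id = ids[i])
      env <- simulate_site_environment(stress[i], n_plants = n_plants,
                                       noise = noise, site_id = ids[i])
      # partition leaflets evenly among plants for plant-level diversity
      plant_of <- sort(rep_len(seq_len(n_plants), n_leaflets))
      lambda <- 0.5 + 1.5 * stress[i] # extra galls per occupied leaflet
      counts <- matrix(0L, nrow(m), ncol(m))
      occ <- which(m == 1)
      counts[occ] <- 1L + stats::rpois(length(occ), lambda)
      galls[[i]] <- data.frame(
        plant_id = paste0(ids[i], "_p", seq_len(n_plants)),
        site_id = ids[i],
        richness = vapply(seq_len(n_plants), function(p) {
          cols <- which(plant_of == p)
          sum(rowSums(m[, cols, drop = FALSE]) > 0)
        }, integer(1)),
        abundance = vapply(seq_len(n_plants), function(p) {
          cols <- which(plant_of == p)
          as.integer(sum(counts[, cols, drop = FALSE]))
        }, integer(1))
      )
      matrices[[ids[i]]] <- m
      environments[[ids[i]]] <- env
    }
    structure(
      list(
        sites = data.frame(site_id = ids, stress_level = stress,
                           theta = theta),
        matrices = matrices,
        environments = environments,
        leaf_disks = do.call(rbind, lapply(environments,
                                           function(e) e$leaf_disks)),
        galls = do.call(rbind, galls),
        ground_truth = list(theta_max = theta_max,
                            occupancy_shift = occupancy_shift,
                            gall_count_lambda = c(0.5, 1.5))
      ),
      class = "gradient_study"
    )
  })
}

#' @export
print.gradient_study <- function(x, ...) {
  cat(sprintf(
    "gradient_study: %d sites, theta_max %.2f (xeric sites: %s)\n",
    nrow(x$sites), x$ground_truth$theta_max,
    paste(x$sites$site_id[x$sites$theta > 0], collapse = ", ")
  ))
  invisible(x)
}

#' Write a gradient study as the CSV dialects the loaders read
#'
#' One matrix CSV per site plus sites/climate/soil/leaf/gall tables, all
#' readable back with [read_gradient_study()].
#'
#' @param study a `gradient_study`.
#' @param dir output directory (created if needed).
#' @export
write_gradient_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- study$sites
  sites$matrix_file <- paste0("matrix_", sites$site_id, ".csv")
  for (i in seq_len(nrow(sites))) {
    write_pa_matrix(study$matrices[[sites$site_id[i]]],
                    file.path(dir, sites$matrix_file[i]))
  }
  utils::write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
  climate <- do.call(rbind, lapply(study$environments, function(e) {
    data.frame(site_id = e$site_id, month = seq_along(e$monthly_precip),
               precip_mm = e$monthly_precip, pet_mm = e$monthly_pet)
  }))
  utils::write.csv(climate, file.path(dir, "climate.csv"), row.names = FALSE)
  soil <- do.call(rbind, lapply(study$environments, function(e) {
    data.frame(site_id = e$site_id, t(e$soil_chemistry))
  }))
  utils::write.csv(soil, file.path(dir, "soil.csv"), row.names = FALSE)
  utils::write.csv(study$leaf_disks, file.path(dir, "leaf.csv"),
                   row.names = FALSE)
  utils::write.csv(study$galls, file.path(dir, "galls.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a gradient study written by [write_gradient_study()]
#'
#' @param dir directory containing sites.csv, climate.csv, soil.csv,
#'   leaf.csv, galls.csv and the per-site matrix CSVs.
#' @return A list with `sites`, `matrices`, `climate`, `soil`, `leaf_disks`,
#'   `galls`.
#' @export
read_gradient_study <- function(dir) {
  sites <- utils::read.csv(file.path(dir, "sites.csv"))
  matrices <- lapply(seq_len(nrow(sites)), function(i) {
    read_pa_matrix(file.path(dir, sites$matrix_file[i]),
                   site_id = sites$site_id[i])
  })
  names(matrices) <- sites$site_id
  list(
    sites = sites,
    matrices = matrices,
    climate = utils::read.csv(file.path(dir, "climate.csv")),
    soil = utils::read.csv(file.path(dir, "soil.csv")),
    leaf_disks = utils::read.csv(file.path(dir, "leaf.csv")),
    galls = utils::read.csv(file.path(dir, "galls.csv"))
  )
}
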