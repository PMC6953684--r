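#' Summarize a null ensemble
#'
#' @param e a `null_ensemble` from [generate_null_ensemble()].
#' @return A list of class `null_summary`: `n`, `mean`, `sd` (denominator
#'   n - 1), `min`, `max`.
#' @export
summarize_null <- function(e) {
  values <- if (inherits(e, "null_ensemble")) e$values else as.numeric(e)
  if (length(values) == 0) stop("empty null ensemble")
  structure(
    list(n = length(values), mean = mean(values),
         sd = if (length(values) > 1) stats::sd(values) else 0,
         min = min(values), max = max(values)),
    class = "null_summary"
  )
}

#' Two one-tailed permutation p-values
#'
#' Following the bi-directional ("bi-flow") report of the randomization test,
#' both tails are returned: `p_ge` is the probability that a null value is at
#' least as large as the observed statistic, `p_le` the probability that it
#' is at least as small. Ties count in both tails, and the observed value is
#' included in the reference set (`+1/(n+1)` correction), so neither p-value
#' can be exactly 0 and `p_ge + p_le >= 1`.
#'
#' @param observed observed statistic value.
#' @param e a `null_ensemble` (or bare numeric vector of null values).
#' @return A list with `p_ge` and `p_le`.
#' @export
tail_p_values <- function(observed, e) {
  values <- if (inherits(e, "null_ensemble")) e$values else as.numeric(e)
  n <- length(values)
  if (n == 0) stop("empty null ensemble")
  list(
    p_ge = (1 + sum(values >= observed)) / (n + 1),
    p_le = (1 + sum(values <= observed)) / (n + 1)
  )
}

#' Normalized and standardized effect sizes
#'
#' `nes = (observed - mean) / mean` (the normalized effect size used to
#' compare sites along the stress gradient) and the classical
#' `ses = (observed - mean) / sd`. Both are computed against the null
#' ensemble's mean and standard deviation.
#'
#' @param observed observed statistic value.
#' @param s a `null_summary` from [summarize_null()] (or a `null_ensemble`,
#'   summarized on the fly).
#' @return A list with `nes` and `ses`; `ses` is `NA` when the null sd is 0.
#' @export
effect_sizes <- function(observed, s) {
  if (inherits(s, "null_ensemble")) s <- summarize_null(s)
  if (s$mean == 0) stop("null mean is 0: NES undefined")
  nes <- (observed - s$mean) / s$mean
  ses <- if (s$sd > 0) (observed - s$mean) / s$sd else NA_real_
  list(nes = nes, ses = ses)
}

#' Full co-occurrence analysis of one site
#'
#' Composes the whole observed-vs-null comparison for one filtered
#' species-by-leaflet matrix: observed [c_score()], fixed-fixed null ensemble
#' ([generate_null_ensemble()]), null summary, two-tailed permutation
#' p-values and both effect sizes. Degenerate (rigid) matrices yield
#' `p_ge = p_le = 1`, `nes = ses = 0` with a warning rather than an error, so
#' multi-site runs survive untestable sites.
#'
#' @param m a [pa_matrix()] with every leaflet galled and every species
#'   present (see [filter_galled_leaflets()], [drop_empty_species()]).
#' @param n_null,burn_in,thin,seed passed to [generate_null_ensemble()].
#' @return A list of class `cooc_result`: `site_id`, `observed`,
#'   `null_summary`, `p_ge`, `p_le`, `nes`, `ses`, `degenerate`, `n_null`,
#'   `seed`.
#' @export
analyze_site <- function(m, n_null = 5000, burn_in = 30000, thin = NULL,
                         seed = NULL) {
  observed <- c_score(m)
  ens <- generate_null_ensemble(m, c_score, n = n_null, burn_in = burn_in,
                                thin = thin, seed = seed)
  summ <- summarize_null(ens)
  if (ens$degenerate) {
    p <- list(p_ge = 1, p_le = 1)
    es <- list(nes = 0, ses = 0)
  } else {
    p <- tail_p_values(observed, ens)
    es <- effect_sizes(observed, summ)
  }
  structure(
    list(site_id = attr(m, "site_id"), observed = observed,
         null_summary = summ, p_ge = p$p_ge, p_le = p$p_le,
         nes = es$nes, ses = es$ses, degenerate = ens$degenerate,
         n_null = ens$n, seed = seed),
    class = "cooc_result"
  )
}

#' @export
print.cooc_result <- function(x, ...) {
  cat(sprintf(
    paste0("cooc_result [%s]: observed C-score %.3f, null %.3f (sd %.3f, ",
           "range %.3f-%.3f)\n  p(obs >= exp) = %.4g, p(obs <= exp) = %.4g, ",
           "NES = %.4f, SES = %.3f%s\n"),
    x$site_id, x$observed, x$null_summary$mean, x$null_summary$sd,
    x$null_summary$min, x$null_summary$max, x$p_ge, x$p_le, x$nes, x$ses,
    if (x$degenerate) " [DEGENERATE]" else ""
  ))
  invisible(x)
}

#' Co-occurrence analysis of several sites
#'
#' Runs [analyze_site()] on each matrix. Each site receives its own random
#' stream, derived from the master seed and a stable hash of the site id, so
#' results do not depend on execution order.
#'
#' @param matrices named list of [pa_matrix()] objects (names are site ids,
#'   falling back to each matrix's `site_id` attribute).
#' @param n_null,burn_in,thin passed to [analyze_site()].
#' @param seed master integer seed.
#' @return A data frame with one row per site: `site_id`, `null_min`,
#'   `null_max`, `null_mean`, `null_sd`, `observed`, `p_ge`, `p_le`, `nes`,
#'   `ses`, `degenerate`, `seed`.
#' @export
analyze_sites <- function(matrices, n_null = 5000, burn_in = 30000,
                          thin = NULL, seed = 1L) {
  ids <- names(matrices)
  if (is.null(ids)) {
    ids <- vapply(matrices, function(m) as.character(attr(m, "site_id")),
                  character(1))
  }
  rows <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    attr(m, "site_id") <- ids[i]
    s <- site_stream_seed(seed, ids[i])
    res <- analyze_site(m, n_null = n_null, burn_in = burn_in, thin = thin,
                        seed = s)
    data.frame(
      site_id = ids[i],
      null_min = res$null_summary$min, null_max = res$null_summary$max,
      null_mean = res$null_summary$mean, null_sd = res$null_summary$sd,
      observed = res$observed, p_ge = res$p_ge, p_le = res$p_le,
      nes = res$nes, ses = res$ses, degenerate = res$degenerate,
      seed = s
    )
  })
  do.call(rbind, rows)
}

#' Write a site-by-site co-occurrence results table
#'
#' Tab-separated table mirroring the per-site randomization report (null
#' minimum/maximum, observed index, both tail p-values) extended with the
#' null mean and sd, NES, SES and the per-site seed.
#'
#' @param results data frame from [analyze_sites()].
#' @param path output TSV path.
#' @export
write_cooc_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
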