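#' One sequential-swap attempt
#'
#' Draws a random 2x2 submatrix (a random pair of distinct rows and a random
#' pair of distinct columns). If the submatrix is a checkerboard
#' (`[[1,0],[0,1]]` or `[[0,1],[1,0]]`) it is flipped to the other
#' checkerboard form; otherwise the matrix is returned unchanged. Both row
#' and column totals are preserved in either case. Rejection is a normal
#' outcome, not an error.
#'
#' Uses R's global random number stream; seed with [set.seed()].
#'
#' @param m a [pa_matrix()] (or plain binary matrix).
#' @return A list with `matrix` (the new state) and `accepted` (logical).
#' @export
swap_step <- function(m) {
  rows <- sample.int(nrow(m), 2L)
  cols <- sample.int(ncol(m), 2L)
  sub <- m[rows, cols]
  accepted <- FALSE
  if ((sub[1, 1] == 1 && sub[2, 2] == 1 && sub[1, 2] == 0 && sub[2, 1] == 0) ||
      (sub[1, 1] == 0 && sub[2, 2] == 0 && sub[1, 2] == 1 && sub[2, 1] == 1)) {
    m[rows, cols] <- 1L - sub
    accepted <- TRUE
  }
  list(matrix = m, accepted = accepted)
}

default_thin <- function(m) max(1000L, 10L * nrow(m) * ncol(m))

#' Fixed-fixed null ensemble of a co-occurrence statistic
#'
#' Runs the sequential-swap Markov chain from the observed matrix — every
#' state shares the observed row and column totals — and records the value of
#' `statistic` on thinned samples. `burn_in` and `thin` count *attempted*
#' swaps; counting attempts (rather than acceptances) makes the chain's
#' proposal symmetric, and each attempt is lazy with probability 1/2 (a
#' self-loop), which guarantees aperiodicity even on matrices where every
#' proposal would be accepted (e.g. a single 2x2 checkerboard). The chain's
#' stationary distribution is therefore uniform over the set of binary
#' matrices with the observed margins.
#'
#' If no swap is accepted during burn-in the margins admit a single matrix
#' (or the chain cannot move); the ensemble is flagged `degenerate` and
#' downstream inference reports p = 1, NES = 0 with a warning.
#'
#' @param m a [pa_matrix()] with at least 2 rows and 2 columns.
#' @param statistic function of a binary matrix; the default [c_score()] uses
#'   a fast compiled path with incremental pair updates.
#' @param n number of null values to collect (study default 5000).
#' @param burn_in attempted swaps before the first sample (default 30000).
#' @param thin attempted swaps between samples; default
#'   `max(1000, 10 * nrow * ncol)`.
#' @param seed optional integer seed (chain is bit-reproducible given it).
#' @param keep `"none"` (default), `"keys"` (flat 0/1 strings identifying
#'   each sampled matrix) or `"matrices"` (full sampled matrices).
#' @return A list of class `null_ensemble`: `statistic_name`, `values`, `n`,
#'   `algorithm`, `burn_in`, `thin`, `seed`, `margins`, `accepted_burnin`,
#'   `accepted_total`, `margin_violations`, `degenerate`, and optionally
#'   `keys`/`matrices`.
#' @export
generate_null_ensemble <- function(m, statistic = c_score, n = 5000,
                                   burn_in = 30000, thin = NULL,
                                   seed = NULL,
                                   keep = c("none", "keys", "matrices")) {
  keep <- match.arg(keep)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("null ensemble needs at least 2 species and 2 leaflets")
  }
  if (is.null(thin)) thin <- default_thin(m)
  use_fast <- identical(statistic, c_score)
  keep_code <- switch(keep, none = 0L, keys = 1L, matrices = 2L)
  if (!use_fast && keep_code == 0L) keep_code <- 2L
  mm <- unclass(m)
  attr(mm, "site_id") <- NULL
  res <- with_seed(seed,
    cpp_swap_chain(mm, as.integer(n), as.integer(burn_in), as.integer(thin),
                   keep_code)
  )
  values <- if (use_fast) {
    res$values
  } else {
    vapply(res$matrices, statistic, numeric(1))
  }
  if (res$margin_violations > 0) {
    stop("internal error: sampled matrix violated the fixed margins")
  }
  out <- list(
    statistic_name = if (use_fast) "c_score" else
      deparse(substitute(statistic))[1],
    values = values,
    n = as.integer(n),
    algorithm = "sequential_swap",
    burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    seed = seed,
    margins = margins(m),
    accepted_burnin = res$accepted_burnin,
    accepted_total = res$accepted_total,
    margin_violations = res$margin_violations,
    degenerate = res$accepted_burnin == 0
  )
  if (keep == "keys") out$keys <- res$keys
  if (keep == "matrices") out$matrices <- res$matrices
  if (out$degenerate) {
    warning("no swap accepted during burn-in: margins admit no alternative ",
            "matrix (degenerate ensemble)")
  }
  class(out) <- "null_ensemble"
  out
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "null_ensemble: %d x %s samples (%s), burn_in %d, thin %d%s\n",
    x$n, x$statistic_name, x$algorithm, x$burn_in, x$thin,
    if (x$degenerate) " [DEGENERATE]" else ""
  ))
  invisible(x)
}

#' Enumerate all binary matrices with given margins
#'
#' Exhaustive column-wise backtracking with feasibility pruning, used as the
#' exact oracle against which the swap sampler is validated. Only practical
#' for small margin sets; a partial-state guard refuses runaway instances.
#'
#' @param row_totals,col_totals non-negative integer margin vectors with
#'   equal sums.
#' @param max_states guard on the number of partial states explored
#'   (default 1e6); exceeding it is an error advising the sampler.
#' @return A list of binary matrices (possibly empty when the margins are
#'   infeasible).
#' @examples
#' length(enumerate_fixed_margin_matrices(c(1, 1), c(1, 1))) # 2
#' @export
enumerate_fixed_margin_matrices <- function(row_totals, col_totals,
                                            max_states = 1e6) {
  row_totals <- as.integer(row_totals)
  col_totals <- as.integer(col_totals)
  if (any(row_totals < 0) || any(col_totals < 0)) {
    stop("margins must be non-negative")
  }
  if (sum(row_totals) != sum(col_totals)) {
    stop("row and column totals must share the same grand total")
  }
  R <- length(row_totals)
  C <- length(col_totals)
  if (any(row_totals > C) || any(col_totals > R)) return(list())
  results <- list()
  states <- 0L
  mat <- matrix(0L, R, C)

  recurse <- function(j, rem) {
    states <<- states + 1L
    if (states > max_states) {
      stop("enumeration guard exceeded (", max_states,
           " partial states): use the swap sampler for margins this large")
    }
    if (j > C) {
      if (all(rem == 0L)) results[[length(results) + 1L]] <<- mat
      return(invisible())
    }
    k <- col_totals[j]
    cand <- which(rem > 0L)
    if (length(cand) < k) return(invisible())
    choices <- if (k == 0L) list(integer(0)) else
      utils::combn(cand, k, simplify = FALSE)
    cols_left <- C - j
    for (rows in choices) {
      rem2 <- rem
      rem2[rows] <- rem2[rows] - 1L
      # each remaining row demand must fit in the remaining columns
      if (all(rem2 <= cols_left)) {
        mat[, j] <<- 0L
        mat[rows, j] <<- 1L
        recurse(j + 1L, rem2)
      }
    }
    mat[, j] <<- 0L
    invisible()
  }
  recurse(1L, row_totals)
  results
}

#' Exact null distribution of a statistic under fixed margins
#'
#' Evaluates `statistic` on every binary matrix sharing `m`'s margins
#' (uniform weight on each), via [enumerate_fixed_margin_matrices()]. This is
#' the reference distribution the sequential-swap sampler targets.
#'
#' @param m a [pa_matrix()] with enumerable margins.
#' @param statistic function of a binary matrix (default [c_score()]).
#' @param max_states passed to the enumerator.
#' @return A list with `support` (data frame: `value`, `probability`),
#'   `n_matrices`, and `values` (one statistic value per enumerated matrix,
#'   in enumeration order).
#' @export
exact_null_distribution <- function(m, statistic = c_score,
                                    max_states = 1e6) {
  mats <- enumerate_fixed_margin_matrices(rowSums(m), colSums(m),
                                          max_states = max_states)
  if (length(mats) == 0) stop("margins admit no binary matrix")
  vals <- vapply(mats, statistic, numeric(1))
  tab <- table(factor(signif(vals, 12)))
  support <- data.frame(
    value = as.numeric(names(tab)),
    probability = as.numeric(tab) / length(vals)
  )
  support <- support[order(support$value), , drop = FALSE]
  rownames(support) <- NULL
  list(support = support, n_matrices = length(mats), values = vals)
}
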