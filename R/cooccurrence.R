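#' Checkerboard units for one species pair
#'
#' For two species with occurrence counts `r_i`, `r_j` sharing `S` leaflets,
#' the number of checkerboard units is `CU = (r_i - S) * (r_j - S)`: the
#' count of leaflet pairs on which the two species form a mutually exclusive
#' "checkerboard" configuration.
#'
#' @param row_i,row_j equal-length binary occurrence vectors (one per
#'   species, over the same leaflets).
#' @return A list of class `pair_cu` with elements `r_i`, `r_j`, `S`, `CU`.
#' @examples
#' checkerboard_units(c(1, 1, 0, 0), c(1, 0, 1, 0)) # CU = 1
#' @export
checkerboard_units <- function(row_i, row_j) {
  if (length(row_i) != length(row_j)) {
    stop("species occurrence vectors differ in length (",
         length(row_i), " vs ", length(row_j), ")")
  }
  if (!all(row_i %in% c(0, 1)) || !all(row_j %in% c(0, 1))) {
    stop("occurrence vectors must be binary")
  }
  r_i <- sum(row_i)
  r_j <- sum(row_j)
  S <- sum(row_i == 1 & row_j == 1)
  structure(list(r_i = r_i, r_j = r_j, S = S, CU = (r_i - S) * (r_j - S)),
            class = "pair_cu")
}

#' Checkerboard units for every species pair of a matrix
#'
#' @param m a [pa_matrix()] (or plain binary matrix) with species as rows.
#' @return A data frame with one row per unordered species pair: labels,
#'   `r_i`, `r_j`, `S`, `CU`.
#' @export
pair_cu_table <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 species rows to form pairs")
  r <- rowSums(m)
  S <- tcrossprod(m)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  data.frame(
    species_i = rownames(m)[idx[, 1]],
    species_j = rownames(m)[idx[, 2]],
    r_i = r[idx[, 1]],
    r_j = r[idx[, 2]],
    S = S[idx],
    CU = (r[idx[, 1]] - S[idx]) * (r[idx[, 2]] - S[idx]),
    row.names = NULL
  )
}

#' C-score of a presence/absence matrix
#'
#' The mean number of checkerboard units over all `R(R-1)/2` unordered
#' species pairs. Higher values indicate a more segregated community; the
#' statistic is invariant under any permutation of rows or columns.
#'
#' @param m a [pa_matrix()] (or plain binary matrix) with species as rows.
#' @return The C-score as a single numeric value.
#' @examples
#' m <- pa_matrix(rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1), C = c(1, 0, 1, 0)))
#' c_score(m) # 2
#' @export
c_score <- function(m) {
  R <- nrow(m)
  if (R < 2) stop("C-score needs at least 2 species rows")
  r <- rowSums(m)
  S <- tcrossprod(m)
  up <- upper.tri(S)
  ri <- matrix(r, R, R)
  cu <- (t(ri)[up] - S[up]) * (ri[up] - S[up])
  sum(cu) / (R * (R - 1) / 2)
}
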