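#' Binary species-by-leaflet presence/absence matrix
#'
#' Constructs and validates the canonical community object of the package: a
#' binary matrix whose rows are gall morphospecies and whose columns are
#' individual leaflets of one host-plant population (site). All co-occurrence
#' statistics are computed over row (species) pairs.
#'
#' @param entries matrix of 0/1 values (numeric, integer or logical). Row
#'   names are species ids, column names leaflet ids; defaults (`sp1...`,
#'   `lf1...`) are supplied when missing.
#' @param site_id label of the site/population the matrix belongs to.
#' @return An integer matrix of class `pa_matrix` with a `site_id` attribute.
#' @examples
#' m <- pa_matrix(rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1), C = c(1, 0, 1, 0)))
#' rowSums(m) # species occurrence counts r_i
#' @export
pa_matrix <- function(entries, site_id = NA_character_) {
  if (!is.matrix(entries)) entries <- as.matrix(entries)
  if (is.logical(entries)) storage.mode(entries) <- "integer"
  if (!is.numeric(entries)) {
    stop("presence/absence entries must be numeric 0/1 values")
  }
  ok <- array(entries %in% c(0, 1), dim = dim(entries))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-binary cell at row '%s', column '%s' (value %s)",
      rownames(entries)[bad[1, 1]] %||% bad[1, 1],
      colnames(entries)[bad[1, 2]] %||% bad[1, 2],
      format(entries[bad[1, 1], bad[1, 2]])
    ))
  }
  storage.mode(entries) <- "integer"
  if (is.null(rownames(entries))) {
    rownames(entries) <- paste0("sp", seq_len(nrow(entries)))
  }
  if (is.null(colnames(entries))) {
    colnames(entries) <- paste0("lf", seq_len(ncol(entries)))
  }
  if (anyDuplicated(rownames(entries))) {
    stop("duplicated species labels: ",
         paste(unique(rownames(entries)[duplicated(rownames(entries))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(entries))) {
    stop("duplicated leaflet labels: ",
         paste(unique(colnames(entries)[duplicated(colnames(entries))]),
               collapse = ", "))
  }
  structure(entries, site_id = site_id, class = c("pa_matrix", class(entries)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf(
    "pa_matrix: %d species x %d leaflets (site: %s), %d occurrences\n",
    nrow(x), ncol(x), attr(x, "site_id"), sum(x)
  ))
  invisible(x)
}

#' Row and column totals of a presence/absence matrix
#'
#' @param m a [pa_matrix()].
#' @return A list with `row_totals` (species occurrence counts r_i) and
#'   `col_totals` (species per leaflet c_j).
#' @export
margins <- function(m) {
  list(row_totals = rowSums(m), col_totals = colSums(m))
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"), function(d) {
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) {
    stop("could not detect a comma, tab or semicolon delimiter in ", path)
  }
  c(",", "\t", ";")[which.max(counts)]
}

#' Read a species-by-leaflet matrix from a delimited text file
#'
#' Expects a header row of leaflet (or species) ids and a first column of
#' species (or leaflet) ids. The delimiter is auto-detected among comma, tab
#' and semicolon. Cell values must parse to 0 or 1.
#'
#' @param path path to the CSV/TSV file.
#' @param orientation `"species_rows"` (default; rows of the file are
#'   species) or `"species_cols"` (the file is transposed on load so that the
#'   returned matrix has species as rows).
#' @param site_id site label; defaults to the file name without extension.
#' @return A validated [pa_matrix()].
#' @export
read_pa_matrix <- function(path,
                           orientation = c("species_rows", "species_cols"),
                           site_id = NULL) {
  orientation <- match.arg(orientation)
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          row.names = 1, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  entries <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(entries), nrow = nrow(entries),
                                 dimnames = dimnames(entries)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 rownames(num)[bad[1]], colnames(num)[bad[2]], path))
  }
  if (orientation == "species_cols") num <- t(num)
  if (is.null(site_id)) {
    site_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pa_matrix(num, site_id = site_id)
}

#' Write a presence/absence matrix to a delimited text file
#'
#' Inverse of [read_pa_matrix()]: header = leaflet ids, first column =
#' species ids.
#'
#' @param m a [pa_matrix()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @export
write_pa_matrix <- function(m, path, sep = ",") {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only galled leaflets
#'
#' Drops columns (leaflets) that host no gall species, mirroring the sampling
#' rule that every analysed leaflet bears at least one gall. Species rows are
#' retained even when they occur on a single leaflet.
#'
#' @param m a [pa_matrix()].
#' @return The filtered `pa_matrix`; a message reports how many leaflets were
#'   removed. Errors if no galled leaflet remains.
#' @export
filter_galled_leaflets <- function(m) {
  keep <- colSums(m) >= 1L
  if (!any(keep)) stop("no galled leaflets: every column total is zero")
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("filter_galled_leaflets: removed %d empty leaflet(s)",
                    removed))
  }
  pa_matrix(m[, keep, drop = FALSE], site_id = attr(m, "site_id"))
}

#' Subsample leaflets without replacement
#'
#' Standardizes matrices to a common number of leaflets (the study design
#' samples 137 galled leaflets per population). Columns are drawn uniformly
#' without replacement; the retained columns keep their original order so
#' that downstream seeded analyses are reproducible. Species rows are left
#' intact and may become all-zero; see [drop_empty_species()].
#'
#' @param m a [pa_matrix()].
#' @param n number of leaflets to keep (default 137).
#' @param seed optional integer seed for the draw.
#' @return A `pa_matrix` with exactly `n` columns.
#' @export
subsample_leaflets <- function(m, n = 137, seed = NULL) {
  if (n > ncol(m)) {
    stop(sprintf("cannot subsample %d leaflets from a matrix with %d", n,
                 ncol(m)))
  }
  keep <- with_seed(seed, sort(sample.int(ncol(m), n)))
  pa_matrix(m[, keep, drop = FALSE], site_id = attr(m, "site_id"))
}

#' Drop species absent from the analysed leaflet set
#'
#' Species whose row total is zero cannot contribute a checkerboard pair;
#' they are removed (and reported) before co-occurrence analysis.
#'
#' @param m a [pa_matrix()].
#' @return A `pa_matrix` whose every row total is at least 1.
#' @export
drop_empty_species <- function(m) {
  keep <- rowSums(m) >= 1L
  if (!all(keep)) {
    message(sprintf("drop_empty_species: removed %d absent species (%s)",
                    sum(!keep), paste(rownames(m)[!keep], collapse = ", ")))
  }
  pa_matrix(m[keep, , drop = FALSE], site_id = attr(m, "site_id"))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit stream seed for a site within a master-seeded run.
site_stream_seed <- function(master_seed, site_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(site_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(master_seed)) %% 2147483647)
}
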