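#' Read a square substitution/similarity matrix in BLAST-style text format
#'
#' First non-comment line holds the column residue letters; each following
#' line a row letter and its integer scores.
#'
#' @param path matrix file; defaults to the bundled PAM250 table (the
#'   classic Dayhoff log-odds integers, the ClustalW default).
#' @return symmetric numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pam250.txt", package = "mosaicphy")
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[[`, character(1), 1L)
  M <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1])))
  dimnames(M) <- list(rows, header)
  if (!isSymmetric(M)) abort_input("substitution matrix must be symmetric")
  M
}

#' Clustal-style conservation quality of one alignment column
#'
#' Each ungapped residue is mapped to a point in 20-dimensional space by its
#' row of the similarity matrix; the consensus is the frequency-weighted
#' mean of those points, and the column's divergence is the mean Euclidean
#' distance of residue points from the consensus. The score is
#' `Q = 100 * max(0, 1 - dbar / norm)`.
#'
#' @param column character vector of residues (one per sequence; `-`/`X`
#'   are excluded from the computation).
#' @param matrix similarity matrix from [read_substitution_matrix()].
#' @param norm normalization constant on the d-bar scale. `NULL` returns the
#'   raw mean distance in the `dbar` field with `q = NA`.
#' @return list with `q` (or `NA` if undefined) and `dbar` (mean distance;
#'   `NA` for an all-gap column).
#' @export
column_quality <- function(column, matrix = read_substitution_matrix(),
                           norm = NULL) {
  res <- toupper(column)
  res <- res[res %in% rownames(matrix)]
  if (length(res) == 0L) return(list(q = NA_real_, dbar = NA_real_))
  pts <- matrix[res, , drop = FALSE]
  consensus <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, consensus)^2))
  dbar <- mean(d)
  q <- if (is.null(norm)) NA_real_ else 100 * max(0, 1 - dbar / norm)
  list(q = q, dbar = dbar)
}

#' Per-column conservation quality profile of an alignment
#'
#' By default the normalization constant is the maximum column mean-distance
#' over the *whole* alignment, computed once, so that partition means drawn
#' from the same profile share a common 0-100 scale.
#'
#' @param aln a [mosaic_msa()].
#' @param matrix similarity matrix.
#' @param norm normalization constant; default max d-bar over all columns.
#' @return tibble with columns `column`, `dbar`, `q`; attribute `norm`.
#' @export
quality_profile <- function(aln, matrix = read_substitution_matrix(),
                            norm = NULL) {
  m <- unclass(aln)
  dbars <- vapply(seq_len(ncol(m)),
                  function(j) column_quality(m[, j], matrix)$dbar,
                  numeric(1))
  if (is.null(norm)) {
    if (all(is.na(dbars))) abort_input("all columns are gaps; no quality defined")
    norm <- max(dbars, na.rm = TRUE)
  }
  q <- if (norm == 0) {
    ifelse(is.na(dbars), NA_real_, 100)   # perfectly conserved throughout
  } else {
    ifelse(is.na(dbars), NA_real_, 100 * pmax(0, 1 - dbars / norm))
  }
  out <- tibble(column = seq_len(ncol(m)), dbar = dbars, q = q)
  attr(out, "norm") <- norm
  out
}

#' Mean conservation quality of a partition
#'
#' @param aln a [mosaic_msa()] (the full scaffold alignment).
#' @param mask a [partition_mask()] selecting the partition's columns.
#' @param matrix similarity matrix.
#' @param profile optional precomputed [quality_profile()] of `aln` (so the
#'   same normalization is reused across partitions).
#' @return one-row tibble: `partition`, `mean_q`, `se_q` (standard error of
#'   the mean), `n_columns` (columns with defined quality).
#' @export
partition_mean_quality <- function(aln, mask,
                                   matrix = read_substitution_matrix(),
                                   profile = NULL) {
  profile <- profile %||% quality_profile(aln, matrix)
  q <- profile$q[profile$column %in% mask$columns]
  q <- q[!is.na(q)]
  if (length(q) == 0L) abort_input("no column in the mask has a defined quality")
  tibble(partition = mask$name,
         mean_q = mean(q),
         se_q = if (length(q) > 1L) sd(q) / sqrt(length(q)) else NA_real_,
         n_columns = length(q))
}
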