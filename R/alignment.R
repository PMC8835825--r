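#' Protein multiple sequence alignments and partition masks
#'
#' An alignment is stored as a character matrix (one row per taxon, one
#' column per alignment position, upper-case residues, `-` for gaps and `X`
#' for unknowns) with unique taxon labels as row names, wrapped in the S3
#' class `mosaic_msa`.
#'
#' @param rows named character vector of equal-length sequences, or a
#'   character matrix of single residues with taxon row names.
#' @return A `mosaic_msa` object.
#' @export
mosaic_msa <- function(rows) {
  if (is.matrix(rows)) {
    m <- rows
  } else {
    if (is.null(names(rows))) abort_input("sequences must be named by taxon")
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L) {
      abort_input(sprintf(
        "ragged alignment: row lengths differ (%s)",
        paste(unique(lens), collapse = ", ")))
    }
    if (lens[1] < 1L) abort_input("alignment must have at least one column")
    m <- do.call(rbind, strsplit(toupper(rows), ""))
    rownames(m) <- names(rows)
  }
  if (anyDuplicated(rownames(m))) abort_input("duplicate taxon labels")
  storage.mode(m) <- "character"
  structure(m, class = c("mosaic_msa", "matrix"))
}

#' @export
print.mosaic_msa <- function(x, ...) {
  cat(sprintf("<mosaic_msa: %d taxa x %d columns>\n", nrow(x), ncol(x)))
  invisible(x)
}

n_taxa <- function(aln) nrow(aln)
n_cols <- function(aln) ncol(aln)
taxa_labels <- function(aln) rownames(aln)

#' Read a protein MSA from FASTA, parsing clade labels
#'
#' Taxon labels are expected to encode the clade (e.g. the aaRS type) as a
#' prefix, `CLADE_species` by default. The text before the first occurrence
#' of any delimiter character is taken as the clade identifier.
#'
#' @param path FASTA file.
#' @param delimiters characters separating clade prefix from the rest of the
#'   label (default `_` and `|`).
#' @return A list with elements `alignment` (a [mosaic_msa()]) and
#'   `clade_map` (a tibble with columns `taxon`, `clade`).
#' @export
read_msa <- function(path, delimiters = c("_", "|")) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) abort_input("empty FASTA file")
  seqs <- setNames(as.character(ss), names(ss))
  aln <- mosaic_msa(seqs)
  list(alignment = aln, clade_map = parse_clade_map(taxa_labels(aln), delimiters))
}

#' Write an alignment to FASTA
#' @param aln a [mosaic_msa()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Derive a clade map from taxon labels
#' @param taxa character vector of taxon labels.
#' @param delimiters delimiter characters; clade = text before the first one.
#' @return tibble with columns `taxon`, `clade`.
#' @export
parse_clade_map <- function(taxa, delimiters = c("_", "|")) {
  rx <- paste0("[", paste(gsub("([|\\\\^\\]\\[-])", "\\\\\\1", delimiters),
                          collapse = ""), "]")
  clade <- vapply(strsplit(taxa, rx), `[[`, character(1), 1L)
  tibble(taxon = taxa, clade = clade)
}

check_clade_map <- function(clade_map, aln) {
  if (!setequal(clade_map$taxon, taxa_labels(aln)) ||
      anyDuplicated(clade_map$taxon)) {
    abort_input("clade map must cover every alignment taxon exactly once")
  }
  invisible(clade_map)
}

#' Partition masks over scaffold columns
#'
#' A mask names a subset of alignment columns together with the segment-unit
#' composition values (A, B, C, CP1) used as regression predictors. Columns
#' are stored 1-based internally; the on-disk config format uses 0-based
#' half-open intervals.
#'
#' @param name mask label.
#' @param columns integer vector of 1-based column indices.
#' @param composition named list/vector with elements `A`, `B`, `C`, `CP1`.
#' @return A `mosaic_mask` object.
#' @export
partition_mask <- function(name, columns,
                           composition = c(A = 0, B = 0, C = 0, CP1 = 0)) {
  columns <- sort(unique(as.integer(columns)))
  if (length(columns) == 0L) abort_input("empty partition mask")
  if (any(columns < 1L)) abort_input("column indices must be >= 1")
  comp <- unlist(composition)[c("A", "B", "C", "CP1")]
  comp[is.na(comp)] <- 0
  names(comp) <- c("A", "B", "C", "CP1")
  structure(list(name = name, columns = columns, composition = comp,
                 numb = length(columns)),
            class = "mosaic_mask")
}

#' @export
print.mosaic_mask <- function(x, ...) {
  cat(sprintf("<mosaic_mask '%s': %d columns, composition A=%g B=%g C=%g CP1=%g>\n",
              x$name, x$numb, x$composition["A"], x$composition["B"],
              x$composition["C"], x$composition["CP1"]))
  invisible(x)
}

#' Read a partition configuration file
#'
#' The YAML config lists named masks as 0-based half-open `[start, end)`
#' column intervals plus their A/B/C/CP1 composition values (see
#' `system.file("extdata", "scaffold_partitions.yaml", package = "mosaicphy")`).
#'
#' @param path YAML file.
#' @return named list of [partition_mask()] objects; the attribute
#'   `segments` holds the raw segment intervals, `n_cols` the scaffold width.
#' @export
read_partition_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  masks <- lapply(names(cfg$masks), function(nm) {
    spec <- cfg$masks[[nm]]
    cols <- intervals_to_columns(spec$intervals)
    partition_mask(nm, cols, spec$composition)
  })
  names(masks) <- names(cfg$masks)
  attr(masks, "segments") <- lapply(cfg$segments, intervals_to_columns)
  attr(masks, "n_cols") <- cfg$n_cols
  masks
}

# 0-based half-open intervals -> 1-based column indices
intervals_to_columns <- function(intervals) {
  cols <- unlist(lapply(intervals, function(iv) {
    if (iv[2] <= iv[1]) abort_input("empty interval in partition config")
    seq.int(iv[1] + 1L, iv[2])
  }))
  sort(unique(as.integer(cols)))
}

#' Extract the sub-alignment selected by a mask
#'
#' @param aln a [mosaic_msa()].
#' @param mask a [partition_mask()].
#' @return a [mosaic_msa()] restricted to the mask's columns (ascending
#'   order); taxa unchanged.
#' @export
apply_partition <- function(aln, mask) {
  if (max(mask$columns) > n_cols(aln)) {
    abort_input("mask columns out of range for this alignment")
  }
  mosaic_msa(unclass(aln)[, mask$columns, drop = FALSE])
}

#' Sample balanced 20-residue control subsets from the urzyme mask
#'
#' Draws `n_subsets` masks, each consisting of `total / block_len`
#' non-overlapping contiguous blocks of `block_len` columns from within the
#' urzyme mask, emulating length-controlled subset alignments. Composition
#' values are computed from the segment each block's columns fall in, in
#' units of `block_len` residues per segment unit.
#'
#' @param urzyme_mask a [partition_mask()] covering the urzyme columns.
#' @param n_subsets number of subset masks (default 7).
#' @param block_len contiguous block length (default 5).
#' @param total columns per subset (default 20); must be divisible by
#'   `block_len`.
#' @param seed integer seed for reproducibility.
#' @param segments optional named list of segment column vectors (`A`, `B`,
#'   `C`) used to derive composition values.
#' @return list of [partition_mask()] named `Urz_0` ... `Urz_<n-1>`.
#' @export
sample_balanced_subsets <- function(urzyme_mask, n_subsets = 7, block_len = 5,
                                    total = 20, seed = 1, segments = NULL) {
  if (total %% block_len != 0) abort_input("total must be divisible by block_len")
  cols <- urzyme_mask$columns
  if (length(cols) < total) abort_input("urzyme mask shorter than subset size")
  n_blocks <- total %/% block_len
  # candidate block starts: positions where block_len consecutive mask columns
  # are contiguous in the scaffold
  run_ok <- vapply(seq_len(length(cols) - block_len + 1L), function(i) {
    cols[i + block_len - 1L] - cols[i] == block_len - 1L
  }, logical(1))
  starts <- which(run_ok)
  if (length(starts) < n_blocks) abort_input("urzyme mask too fragmented for block sampling")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  out <- vector("list", n_subsets)
  for (s in seq_len(n_subsets)) {
    chosen <- integer(0)
    taken <- logical(length(cols))
    avail <- starts
    for (b in seq_len(n_blocks)) {
      ok <- avail[vapply(avail, function(i) !any(taken[i:(i + block_len - 1L)]),
                         logical(1))]
      if (length(ok) == 0L) abort_input("could not place non-overlapping blocks")
      i <- ok[sample.int(length(ok), 1L)]
      taken[i:(i + block_len - 1L)] <- TRUE
      chosen <- c(chosen, cols[i:(i + block_len - 1L)])
    }
    comp <- c(A = 0, B = 0, C = 0, CP1 = 0)
    if (!is.null(segments)) {
      for (seg in intersect(names(segments), names(comp))) {
        comp[seg] <- sum(chosen %in% segments[[seg]]) / block_len
      }
    }
    out[[s]] <- partition_mask(sprintf("Urz_%d", s - 1L), chosen, comp)
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

# Seed hygiene: set a local RNG seed and restore global state afterwards.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Assemble one design-matrix row for a partition
#'
#' Combines a mask's composition with its measured metrics into the row
#' format of the regression design matrix. Derived predictors: `urzyme`
#' (1 if the mask contains any A/B/C column content, i.e. any non-zero
#' A, B or C composition), `protozyme` (1 if A > 0) and `protozyme_n`
#' (the numeric A value). Missing metrics stay `NA`, never zero.
#'
#' @param mask a [partition_mask()].
#' @param s_wag,s_lg mean clade support under WAG / LG (may be `NA`).
#' @param q mean conservation quality.
#' @param tree_height posterior mean tree height.
#' @param shape posterior mean gamma shape.
#' @return one-row tibble in design-matrix column order.
#' @export
assemble_design_row <- function(mask, s_wag = NA_real_, s_lg = NA_real_,
                                q = NA_real_, tree_height = NA_real_,
                                shape = NA_real_) {
  comp <- mask$composition
  tibble(
    Subset = mask$name,
    S_WAG = s_wag, S_LG = s_lg, Q = q,
    TreeHeight = tree_height, Shape = shape,
    A = unname(comp["A"]), B = unname(comp["B"]),
    C = unname(comp["C"]), CP1 = unname(comp["CP1"]),
    NUMB = mask$numb,
    urzyme = as.integer(comp["A"] + comp["B"] + comp["C"] > 0),
    protozyme = as.integer(comp["A"] > 0),
    protozyme_n = unname(comp["A"])
  )
}

#' The reference design matrix shipped with the package
#'
#' Eleven partition rows (full scaffold, urzyme, protozyme, CP1 and seven
#' 20-residue urzyme subsets) with their clade support under WAG and LG,
#' conservation quality, tree height, gamma shape and composition
#' predictors, plus the derived indicator columns.
#'
#' @return tibble with one row per partition.
#' @export
reference_design_matrix <- function() {
  path <- system.file("extdata", "table1_design.csv", package = "mosaicphy")
  d <- as_tibble(read.csv(path, check.names = FALSE))
  dplyr::mutate(d,
    urzyme = as.integer(.data$A + .data$B + .data$C > 0),
    protozyme = as.integer(.data$A > 0),
    protozyme_n = .data$A)
}

#' Write a design matrix as CSV in the reference column order
#' @param design tibble from [assemble_design_row()] rows or
#'   [reference_design_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(design, path) {
  lead <- c("Subset", "S_WAG", "S_LG", "Q", "TreeHeight", "Shape",
            "A", "B", "C", "CP1", "NUMB")
  design <- design[, c(lead, setdiff(names(design), lead))]
  write.csv(design, path, row.names = FALSE, na = "")
  invisible(path)
}
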