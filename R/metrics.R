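#' Test monophyly of a taxon set on a rooted tree
#'
#' True iff some node's complete descendant leaf set equals `taxa` (rooted
#' convention). A singleton taxon is monophyletic by convention. With
#' `rooted = FALSE` the test is bipartition-based: true iff the taxon set
#' (or its complement) forms one side of some branch, the convention for
#' externally supplied unrooted trees.
#'
#' @param tree a [timetree()] or ape `phylo`.
#' @param taxa character vector of leaf labels.
#' @param rooted use the rooted clade convention (default `TRUE`).
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa, rooted = TRUE) {
  labels <- if (inherits(tree, "mosaic_timetree")) tree$tip_labels else tree$tip.label
  idx <- match(taxa, labels)
  if (anyNA(idx)) abort_input("unknown leaf label in clade")
  if (length(idx) == 0L) abort_input("empty taxon set")
  if (length(idx) == 1L) return(TRUE)
  sets <- node_leaf_sets(tree)
  target <- sort(idx)
  hit <- any(vapply(sets, function(s) {
    length(s) == length(target) && all(sort(s) == target)
  }, logical(1)))
  if (hit || rooted) return(hit)
  comp <- sort(setdiff(seq_along(labels), target))
  if (length(comp) <= 1L) return(TRUE)   # trivial split
  any(vapply(sets, function(s) {
    length(s) == length(comp) && all(sort(s) == comp)
  }, logical(1)))
}

# list of descendant tip-index sets, one per internal node
node_leaf_sets <- function(tree) {
  if (inherits(tree, "mosaic_timetree")) {
    sets <- descendant_tips(tree)
    return(sets[which(tree$child1 > 0L)])
  }
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  sets <- vector("list", m)
  for (i in seq_len(n)) sets[[i]] <- i
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]; ch <- edge[r, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[(n + 1L):m]
}

#' Clade monophyly support over a tree ensemble
#'
#' For each clade, the fraction of trees in which it is monophyletic; the
#' mean over clades is the mean support S. Each tree's node leaf-sets are
#' hashed once and every clade is membership-tested against them.
#'
#' @param trees list of [timetree()]s, a `mosaic_posterior`, or a
#'   `multiPhylo`.
#' @param clade_map tibble with columns `taxon`, `clade`.
#' @param rooted rooted clade convention (see [is_monophyletic()]).
#' @return tibble with one row per clade (`clade`, `n_taxa`, `support`);
#'   attributes `mean_support` and `n_trees`.
#' @export
clade_support <- function(trees, clade_map, rooted = TRUE) {
  if (inherits(trees, "mosaic_posterior")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) abort_input("empty tree ensemble")
  labels0 <- tree_labels(trees[[1]])
  clades <- split(clade_map$taxon, clade_map$clade)
  counts <- setNames(numeric(length(clades)), names(clades))
  for (tr in trees) {
    labels <- tree_labels(tr)
    if (!setequal(labels, labels0)) abort_input("trees have differing leaf sets")
    sets <- node_leaf_sets(tr)
    keys <- vapply(sets, function(s) paste(sort(labels[s]), collapse = "\r"),
                   character(1))
    for (cl in names(clades)) {
      tx <- clades[[cl]]
      if (anyNA(match(tx, labels))) abort_input("unknown leaf label in clade map")
      hit <- if (length(tx) == 1L) TRUE else {
        key <- paste(sort(tx), collapse = "\r")
        key %in% keys ||
          (!rooted && paste(sort(setdiff(labels, tx)), collapse = "\r") %in% keys)
      }
      counts[cl] <- counts[cl] + hit
    }
  }
  out <- tibble(clade = names(clades),
                n_taxa = lengths(clades)[names(clades)],
                support = unname(counts) / length(trees))
  attr(out, "mean_support") <- mean(out$support)
  attr(out, "n_trees") <- length(trees)
  out
}

tree_labels <- function(tree) {
  if (inherits(tree, "mosaic_timetree")) tree$tip_labels else tree$tip.label
}

#' Mean clade support of an ensemble
#' @param support result of [clade_support()].
#' @return scalar mean support S.
#' @export
mean_support <- function(support) attr(support, "mean_support")

#' Posterior summaries of tree height and gamma shape from a trace
#'
#' @param trace tibble/data frame with columns `treeHeight` and
#'   `gammaShape` (a `mosaic_posterior` is accepted and its retained trace
#'   used directly with `burnin_fraction = 0`, since burn-in was already
#'   discarded at sampling time).
#' @param burnin_fraction additional leading fraction of records to drop.
#' @param ess_warn warn when an ESS falls below this (default 100).
#' @return one-row tibble: posterior means `tree_height` and `shape`, their
#'   ESS, and `n_used`.
#' @export
summarize_trace <- function(trace, burnin_fraction = 0, ess_warn = 100) {
  if (inherits(trace, "mosaic_posterior")) trace <- trace$trace
  n <- nrow(trace)
  drop <- floor(n * burnin_fraction)
  if (n - drop < 1L) abort_input("no trace records left after burn-in")
  tr <- trace[(drop + 1L):n, , drop = FALSE]
  e_h <- ess(tr$treeHeight)
  e_a <- ess(tr$gammaShape)
  if (any(is.na(c(e_h, e_a)) | c(e_h, e_a) < ess_warn)) {
    # NA = degenerate (constant) trace
    warning(sprintf("ESS below %d; chain may be too short", ess_warn),
            call. = FALSE)
  }
  tibble(tree_height = mean(tr$treeHeight), shape = mean(tr$gammaShape),
         ess_height = e_h, ess_alpha = e_a, n_used = nrow(tr))
}

#' Read a tree ensemble from NEXUS or newline-delimited Newick
#'
#' BEAST-style bracketed branch annotations are stripped before parsing.
#'
#' @param path trees file.
#' @return `multiPhylo`.
#' @export
read_tree_ensemble <- function(path) {
  txt <- readLines(path)
  is_nexus <- any(grepl("#NEXUS", txt, ignore.case = TRUE))
  txt <- gsub("\\[&[^]]*\\]", "", txt)
  tmp <- tempfile(fileext = if (is_nexus) ".nex" else ".nwk")
  writeLines(txt, tmp)
  on.exit(unlink(tmp))
  trees <- if (is_nexus) ape::read.nexus(tmp) else ape::read.tree(tmp)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  trees
}
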