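#' Rooted binary time-trees
#'
#' Internal representation used by the sampler: nodes `1..(2n-1)` with tips
#' `1..n` at height 0; `parent[i] == 0` marks the root, `child1/child2 == 0`
#' mark tips. Heights are in expected substitutions per site (strict clock,
#' rate 1), so the root height is directly the tree-height metric.
#'
#' @param parent,child1,child2 integer node pointers.
#' @param height numeric node heights.
#' @param tip_labels taxon labels for tips `1..n`.
#' @return A `mosaic_timetree`.
#' @export
timetree <- function(parent, child1, child2, height, tip_labels) {
  tt <- structure(list(parent = as.integer(parent),
                       child1 = as.integer(child1),
                       child2 = as.integer(child2),
                       height = as.numeric(height),
                       tip_labels = tip_labels,
                       n_tips = length(tip_labels),
                       root = which(parent == 0L)),
                  class = "mosaic_timetree")
  validate_timetree(tt)
  tt
}

#' @export
print.mosaic_timetree <- function(x, ...) {
  cat(sprintf("<mosaic_timetree: %d tips, root height %.4g>\n",
              x$n_tips, x$height[x$root]))
  invisible(x)
}

validate_timetree <- function(tt) {
  n <- tt$n_tips
  if (length(tt$root) != 1L) abort_input("tree must have exactly one root")
  if (length(tt$parent) != 2L * n - 1L && n > 1L) {
    abort_input("a binary tree on n tips has 2n-1 nodes")
  }
  internal <- which(tt$child1 > 0L)
  for (i in internal) {
    for (ch in c(tt$child1[i], tt$child2[i])) {
      if (tt$height[i] <= tt$height[ch]) {
        abort_input("parent height must exceed child height")
      }
    }
  }
  if (any(abs(tt$height[seq_len(n)]) > 1e-12)) {
    abort_input("tip heights must be 0")
  }
  invisible(tt)
}

#' Root height of a time-tree
#' @param tt a [timetree()].
#' @return numeric root height.
#' @export
tree_height <- function(tt) tt$height[tt$root]

#' Convert a time-tree to an ape phylo object
#' @param tt a [timetree()].
#' @return rooted ultrametric `phylo`.
#' @export
timetree_to_phylo <- function(tt) {
  n <- tt$n_tips
  internal <- which(tt$child1 > 0L)
  # ape numbering: tips 1..n, root n+1, other internals n+2..
  ape_id <- integer(length(tt$parent))
  ape_id[seq_len(n)] <- seq_len(n)
  ape_id[tt$root] <- n + 1L
  rest <- setdiff(internal, tt$root)
  ape_id[rest] <- n + 1L + seq_along(rest)
  edges <- matrix(0L, 2L * n - 2L, 2L)
  lens <- numeric(2L * n - 2L)
  r <- 0L
  for (i in internal) {
    for (ch in c(tt$child1[i], tt$child2[i])) {
      r <- r + 1L
      edges[r, ] <- c(ape_id[i], ape_id[ch])
      lens[r] <- tt$height[i] - tt$height[ch]
    }
  }
  phy <- structure(list(edge = edges, edge.length = lens,
                        tip.label = tt$tip_labels, Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

#' Convert a rooted binary (ultrametric) phylo to a time-tree
#'
#' Node heights are taken as (max root-to-tip depth) minus depth; small
#' deviations from ultrametricity are absorbed by clamping tips to zero and
#' enforcing a minimal parent-child gap.
#'
#' @param phy a rooted, binary `phylo` with edge lengths.
#' @param min_gap minimal parent-above-child height gap.
#' @return a [timetree()].
#' @export
timetree_from_phylo <- function(phy, min_gap = 1e-8) {
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    abort_input("tree must be rooted and binary")
  }
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth) - depth
  height[seq_len(n)] <- 0
  parent <- integer(m); child1 <- integer(m); child2 <- integer(m)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1]; ch <- phy$edge[r, 2]
    parent[ch] <- p
    if (child1[p] == 0L) child1[p] <- ch else child2[p] <- ch
  }
  # enforce strict height ordering bottom-up
  ord <- order(height[(n + 1L):m]) + n
  for (i in ord) {
    hmax <- max(height[c(child1[i], child2[i])])
    if (height[i] <= hmax) height[i] <- hmax + min_gap
  }
  timetree(parent, child1, child2, height, phy$tip.label)
}

#' UPGMA starting tree from an alignment
#'
#' Average-linkage clustering on normalized Hamming distances, used to
#' initialize the sampler near a reasonable ultrametric topology.
#'
#' @param aln a [mosaic_msa()].
#' @return a [timetree()].
#' @export
upgma_start_tree <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% AA_ALPHABET & m[j, ] %in% AA_ALPHABET
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0.5
    # Jukes-Cantor-style correction keeps deep starts from collapsing
    p <- min(p, 0.94)
    d[i, j] <- d[j, i] <- -19 / 20 * log(1 - 20 / 19 * p)
  }
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  phy$edge.length <- pmax(phy$edge.length, 1e-6)
  timetree_from_phylo(ape::reorder.phylo(phy))
}

# descendant tip index sets for every node (list over nodes)
descendant_tips <- function(tt) {
  m <- length(tt$parent)
  sets <- vector("list", m)
  for (i in seq_len(tt$n_tips)) sets[[i]] <- i
  ord <- order(tt$height[(tt$n_tips + 1L):m]) + tt$n_tips
  for (i in ord) {
    sets[[i]] <- c(sets[[tt$child1[i]]], sets[[tt$child2[i]]])
  }
  sets
}
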