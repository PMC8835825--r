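#' Configuration for a synthetic mosaic scaffold dataset
#'
#' The generator emulates a structure-based scaffold alignment: `n_clades`
#' protein-type clades of `taxa_per_clade` sequences evolve on a two-level
#' base tree (deep clade stems, shallower within-clade radiations). Each
#' partition is simulated with its own rate multiplier and gamma shape;
#' partitions with `transplants > 0` evolve on a perturbed copy of the base
#' tree in which leaves were regrafted across clade boundaries, giving that
#' partition a distinct genetic history that degrades clade monophyly (the
#' mosaicity signature). Defaults mirror the scaffold study design: 10
#' clades x 20 taxa, 103 columns split A/B/C/CP1 = 46/17/20/20, a
#' slower-evolving CP1 analog with high shape (uniform site rates) and six
#' transplants, urzyme-analog partitions with shape 1.5 on the clean tree.
#'
#' @param n_clades number of clades.
#' @param taxa_per_clade taxa per clade.
#' @param partitions tibble/data.frame with columns `name`, `n_cols`,
#'   `rate`, `alpha`, `transplants`.
#' @param model substitution model name.
#' @param base_height root height of the base tree (expected
#'   substitutions/site at rate 1).
#' @param crown_frac fraction of the root height below which the
#'   within-clade radiations sit.
#' @return a `mosaic_config` list.
#' @export
mosaic_config <- function(n_clades = 10, taxa_per_clade = 20,
                          partitions = default_partitions(),
                          model = "WAG", base_height = 1,
                          crown_frac = 0.25) {
  partitions <- as_tibble(partitions)
  stopifnot(all(c("name", "n_cols", "rate", "alpha", "transplants") %in%
                  names(partitions)))
  if (any(partitions$rate <= 0) || any(partitions$alpha <= 0) ||
      any(partitions$transplants < 0)) {
    abort_input("rates and alphas must be > 0, transplants >= 0")
  }
  structure(list(n_clades = n_clades, taxa_per_clade = taxa_per_clade,
                 partitions = partitions, model = model,
                 base_height = base_height, crown_frac = crown_frac),
            class = "mosaic_config")
}

#' @rdname mosaic_config
#' @export
default_partitions <- function() {
  tibble(name = c("A", "B", "C", "CP1"),
         n_cols = c(46L, 17L, 20L, 20L),
         rate = c(1, 1, 1, 0.5),
         alpha = c(1.5, 1.5, 1.5, 4.5),
         transplants = c(0L, 0L, 0L, 6L))
}

#' Simulate a two-level clade-structured base time-tree
#'
#' A random coalescent-style topology over clade stems occupies
#' `(crown_frac, 1] * base_height`; each clade's within-clade radiation is a
#' random topology with heights below `crown_frac * base_height`. Every
#' clade is monophyletic by construction.
#'
#' @param n_clades,taxa_per_clade counts (>= 1).
#' @param seed integer seed.
#' @param base_height root height.
#' @param crown_frac stem/crown boundary as a fraction of `base_height`.
#' @return list with `tree` (a [timetree()]) and `clade_map` (tibble).
#' @export
simulate_base_tree <- function(n_clades = 10, taxa_per_clade = 20, seed = 1,
                               base_height = 1, crown_frac = 0.25) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  clades <- sprintf("C%02d", seq_len(n_clades))
  labels <- as.vector(vapply(clades, function(cl) {
    sprintf("%s_t%02d", cl, seq_len(taxa_per_clade))
  }, character(taxa_per_clade)))
  n <- n_clades * taxa_per_clade
  if (n == 1L) {
    tt <- timetree(0L, 0L, 0L, 0, labels)
    return(list(tree = tt, clade_map = parse_clade_map(labels)))
  }
  m <- 2L * n - 1L
  parent <- integer(m); child1 <- integer(m); child2 <- integer(m)
  height <- numeric(m)
  next_node <- n + 1L
  crown <- crown_frac * base_height

  join <- function(active, heights) {
    # random sequential coalescence of `active` nodes at given sorted heights
    for (h in heights) {
      pick <- sample.int(length(active), 2L)
      a <- active[pick[1]]; b <- active[pick[2]]
      nd <- next_node; next_node <<- next_node + 1L
      parent[a] <<- nd; parent[b] <<- nd
      child1[nd] <<- a; child2[nd] <<- b
      height[nd] <<- h
      active <- c(active[-pick], nd)
    }
    active
  }

  clade_roots <- integer(n_clades)
  for (ci in seq_len(n_clades)) {
    tips <- ((ci - 1L) * taxa_per_clade + 1L):(ci * taxa_per_clade)
    if (taxa_per_clade == 1L) {
      clade_roots[ci] <- tips
    } else {
      hs <- sort(runif(taxa_per_clade - 1L, 0.05 * crown, 0.9 * crown))
      clade_roots[ci] <- join(tips, hs)
    }
  }
  if (n_clades == 1L) {
    root <- clade_roots
  } else {
    hs <- sort(runif(n_clades - 2L, 1.02 * crown, 0.98 * base_height))
    active <- join(clade_roots, hs)
    root <- join(active, base_height)
  }
  used <- seq_len(next_node - 1L)
  tt <- timetree(parent[used], child1[used], child2[used], height[used], labels)
  list(tree = tt, clade_map = parse_clade_map(labels))
}

#' Prune-and-regraft transplant perturbation across clade boundaries
#'
#' Moves `m` random leaves from their clade into a different clade's
#' subtree (attachment height uniform on the receiving edge), giving the
#' perturbed tree a genetic history inconsistent with the clade map.
#'
#' @param tt a [timetree()].
#' @param clade_map tibble mapping taxa to clades.
#' @param m number of transplants (>= 0); `m = 0` returns `tt` unchanged.
#' @param seed integer seed.
#' @return list with `tree` and `log` (tibble: leaf, from_clade, to_clade).
#' @export
transplant_perturb <- function(tt, clade_map, m = 0, seed = 1) {
  log <- tibble(leaf = character(0), from_clade = character(0),
                to_clade = character(0))
  if (m == 0) return(list(tree = tt, log = log))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  clade_of <- setNames(clade_map$clade, clade_map$taxon)
  for (rep in seq_len(m)) {
    leaf <- sample.int(tt$n_tips, 1L)
    from <- clade_of[[tt$tip_labels[leaf]]]
    # receiving edges: edges above leaves of a different clade
    other_tips <- which(clade_of[tt$tip_labels[seq_len(tt$n_tips)]] != from)
    other_tips <- setdiff(other_tips, leaf)
    target <- other_tips[sample.int(length(other_tips), 1L)]
    to <- clade_of[[tt$tip_labels[target]]]
    tt <- regraft_leaf(tt, leaf, target)
    log <- dplyr::bind_rows(log, tibble(leaf = tt$tip_labels[leaf],
                                        from_clade = from, to_clade = to))
  }
  list(tree = tt, log = log)
}

# detach `leaf` and reattach on the edge above `target`, at a uniform height
regraft_leaf <- function(tt, leaf, target) {
  p <- tt$parent[leaf]
  g <- tt$parent[p]
  sib <- if (tt$child1[p] == leaf) tt$child2[p] else tt$child1[p]
  if (g == 0L) {             # p is root: sibling becomes the new root
    tt$parent[sib] <- 0L
    tt$root <- sib
  } else {
    if (tt$child1[g] == p) tt$child1[g] <- sib else tt$child2[g] <- sib
    tt$parent[sib] <- g
  }
  pj <- tt$parent[target]
  if (pj == p) pj <- tt$parent[p]   # degenerate; cannot happen for leaf targets
  upper <- tt$height[pj]
  lower <- tt$height[target]
  h <- runif(1, lower + 0.25 * (upper - lower), upper)
  if (tt$child1[pj] == target) tt$child1[pj] <- p else tt$child2[pj] <- p
  tt$parent[p] <- pj
  tt$child1[p] <- leaf
  tt$child2[p] <- target
  tt$parent[target] <- p
  tt$parent[leaf] <- p
  tt$height[p] <- h
  tt$root <- which(tt$parent == 0L)
  tt
}

#' Simulate an alignment along a time-tree
#'
#' Root states are drawn from the model's stationary frequencies; states
#' evolve down branches with transition probabilities
#' `P(rate * r_site * t)`, per-site rates drawn from the discrete gamma
#' distribution with shape `alpha_true`. Indel-free (the scaffold design
#' excludes loops and indels).
#'
#' @param tt a [timetree()].
#' @param n_cols number of columns (>= 1).
#' @param rate partition rate multiplier (>= 0).
#' @param alpha_true gamma shape used in simulation.
#' @param model a [substitution_model()] or model name.
#' @param seed integer seed.
#' @param k discrete gamma categories.
#' @return a [mosaic_msa()].
#' @export
simulate_alignment <- function(tt, n_cols, rate = 1, alpha_true = 1.5,
                               model = "WAG", seed = 1, k = 4) {
  if (n_cols < 1) abort_input("n_cols must be >= 1")
  if (is.character(model)) model <- substitution_model(model, alpha_true, k)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  rates <- discrete_gamma_rates(alpha_true, k)
  site_rate <- rate * sample(rates, n_cols, replace = TRUE)
  m <- length(tt$parent)
  states <- matrix(0L, m, n_cols)
  root <- tt$root
  states[root, ] <- sample.int(20L, n_cols, replace = TRUE,
                               prob = model$freqs)
  # preorder: parents before children
  ord <- order(tt$height, decreasing = TRUE)
  ord <- ord[ord != root]
  uniq_rates <- unique(site_rate)
  for (nd in ord) {
    t_branch <- tt$height[tt$parent[nd]] - tt$height[nd]
    for (r in uniq_rates) {
      js <- which(site_rate == r)
      P <- transition_prob_single(model, r * t_branch)
      from <- states[tt$parent[nd], js]
      states[nd, js] <- vapply(from, function(a) {
        sample.int(20L, 1L, prob = P[a, ])
      }, integer(1))
    }
  }
  chars <- matrix(AA_ALPHABET[states[seq_len(tt$n_tips), , drop = FALSE]],
                  tt$n_tips, n_cols)
  rownames(chars) <- tt$tip_labels
  mosaic_msa(chars)
}

# single P(t) at rate multiplier already applied
transition_prob_single <- function(model, t) {
  if (t <= 0) return(diag(20))
  sq <- sqrt(model$freqs)
  E <- model$eigvec %*% (exp(model$eigval * t) * t(model$eigvec))
  P <- (1 / sq) * E %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Generate a full synthetic mosaic dataset with ground truth
#'
#' Simulates each configured partition on the base tree (or, for
#' partitions with transplants, on its perturbed copy), concatenates them
#' into one scaffold alignment, and returns the partition masks, clade map
#' and truth record.
#'
#' @param config a [mosaic_config()].
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return list: `alignment` ([mosaic_msa()]), `masks` (named list of
#'   [partition_mask()], one per partition plus `Full` and `urzyme` =
#'   union of the non-transplanted partitions named A/B/C), `clade_map`,
#'   and `truth` (trees, per-partition parameters, transplant logs).
#' @export
generate_mosaic_dataset <- function(config = mosaic_config(), seed = 1) {
  base <- simulate_base_tree(config$n_clades, config$taxa_per_clade,
                             seed = seed, base_height = config$base_height,
                             crown_frac = config$crown_frac)
  parts <- config$partitions
  aln_blocks <- vector("list", nrow(parts))
  masks <- vector("list", nrow(parts))
  truth_parts <- vector("list", nrow(parts))
  offset <- 0L
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    pseed <- seed * 1000L + i
    if (p$transplants > 0) {
      pert <- transplant_perturb(base$tree, base$clade_map, p$transplants,
                                 seed = pseed)
      tree_i <- pert$tree
      tlog <- pert$log
    } else {
      tree_i <- base$tree
      tlog <- NULL
    }
    aln_blocks[[i]] <- simulate_alignment(tree_i, p$n_cols, p$rate, p$alpha,
                                          config$model, seed = pseed + 500L)
    comp <- c(A = 0, B = 0, C = 0, CP1 = 0)
    if (p$name %in% names(comp)) comp[p$name] <- 1
    masks[[i]] <- partition_mask(p$name, offset + seq_len(p$n_cols), comp)
    truth_parts[[i]] <- list(name = p$name, rate = p$rate, alpha = p$alpha,
                             transplants = p$transplants, tree = tree_i,
                             transplant_log = tlog)
    offset <- offset + p$n_cols
  }
  names(masks) <- parts$name
  aln <- mosaic_msa(do.call(cbind, lapply(aln_blocks, unclass)))
  clean <- parts$name[parts$transplants == 0]
  urz_cols <- unlist(lapply(masks[clean], `[[`, "columns"))
  masks$urzyme <- partition_mask("urzyme", urz_cols,
                                 sapply(c("A", "B", "C", "CP1"), function(s)
                                   as.numeric(s %in% clean)))
  masks$Full <- partition_mask("Full", seq_len(offset),
                               c(A = 1, B = 1, C = 1, CP1 = 1))
  list(alignment = aln, masks = masks, clade_map = base$clade_map,
       truth = list(base_tree = base$tree, partitions = truth_parts,
                    config = config, seed = seed))
}

#' Write a mosaic dataset to disk
#'
#' FASTA alignment, partition YAML (0-based half-open intervals), clade-map
#' TSV, truth-record JSON, generating trees as Newick.
#'
#' @param dataset result of [generate_mosaic_dataset()].
#' @param dir output directory (created if needed).
#' @return invisible vector of files written.
#' @export
write_mosaic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_fa <- file.path(dir, "alignment.fasta")
  write_msa(dataset$alignment, f_fa)
  f_yaml <- file.path(dir, "partitions.yaml")
  masks_yaml <- lapply(dataset$masks, function(m) {
    list(intervals = columns_to_intervals(m$columns),
         composition = as.list(m$composition))
  })
  yaml::write_yaml(list(n_cols = n_cols(dataset$alignment),
                        masks = masks_yaml), f_yaml)
  f_tsv <- file.path(dir, "clades.tsv")
  utils::write.table(dataset$clade_map, f_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_json <- file.path(dir, "truth.json")
  truth <- dataset$truth
  jsonlite::write_json(list(
    seed = truth$seed,
    partitions = lapply(truth$partitions, function(p) {
      p[c("name", "rate", "alpha", "transplants")]
    })), f_json, auto_unbox = TRUE, pretty = TRUE)
  f_nwk <- file.path(dir, "trees.nwk")
  trees <- lapply(truth$partitions, function(p) timetree_to_phylo(p$tree))
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, f_nwk)
  invisible(c(f_fa, f_yaml, f_tsv, f_json, f_nwk))
}

# 1-based columns -> 0-based half-open intervals
columns_to_intervals <- function(cols) {
  cols <- sort(cols)
  breaks <- which(diff(cols) > 1L)
  starts <- cols[c(1L, breaks + 1L)]
  ends <- cols[c(breaks, length(cols))]
  mapply(function(s, e) c(s - 1L, e), starts, ends, SIMPLIFY = FALSE)
}
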