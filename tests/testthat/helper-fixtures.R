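# Hand-built trees and an independent likelihood oracle used across tests.

# three-taxon time-tree: ((a,b):h_ab, c) with root at h_root
tree3 <- function(h_ab = 0.3, h_root = 0.9, labels = c("a", "b", "c")) {
  timetree(parent = c(5L, 5L, 4L, 0L, 4L),
           child1 = c(0L, 0L, 0L, 5L, 1L),
           child2 = c(0L, 0L, 0L, 3L, 2L),
           height = c(0, 0, 0, h_root, h_ab),
           tip_labels = labels)
}

# four-taxon balanced time-tree: ((a,b):h1, (c,d):h2) root h_root
tree4 <- function(h1 = 0.2, h2 = 0.35, h_root = 0.8,
                  labels = c("a", "b", "c", "d")) {
  timetree(parent = c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
           child1 = c(0L, 0L, 0L, 0L, 6L, 1L, 3L),
           child2 = c(0L, 0L, 0L, 0L, 7L, 2L, 4L),
           height = c(0, 0, 0, 0, h_root, h1, h2),
           tip_labels = labels)
}

# Exhaustive-enumeration likelihood oracle: sums over every assignment of
# states to internal nodes, averaging the gamma categories. Independent of
# the pruning implementation (direct probability bookkeeping in R).
enum_loglik <- function(tt, aln, model) {
  m <- unclass(aln)
  m <- m[match(tt$tip_labels, rownames(m)), , drop = FALSE]
  internals <- which(tt$child1 > 0L)
  nonroot <- which(tt$parent > 0L)
  k <- length(model$rates)
  total <- 0
  for (j in seq_len(ncol(m))) {
    col_lik <- 0
    for (c_ in seq_len(k)) {
      P <- lapply(seq_along(tt$parent), function(nd) {
        if (tt$parent[nd] == 0L) return(NULL)
        t_br <- (tt$height[tt$parent[nd]] - tt$height[nd]) * model$rates[c_]
        mosaicphy:::transition_prob_single(model, t_br)
      })
      grid <- expand.grid(rep(list(1:20), length(internals)))
      s_cat <- 0
      for (g in seq_len(nrow(grid))) {
        state <- integer(length(tt$parent))
        state[internals] <- as.integer(grid[g, ])
        for (tip in seq_len(tt$n_tips)) {
          state[tip] <- match(m[tip, j], mosaicphy:::AA_ALPHABET)
        }
        pr <- model$freqs[[state[tt$root]]]
        for (nd in nonroot) {
          if (is.na(state[nd])) next   # gap/unknown tip: factor sums to 1
          pr <- pr * P[[nd]][state[tt$parent[nd]], state[nd]]
        }
        s_cat <- s_cat + pr
      }
      col_lik <- col_lik + s_cat / k
    }
    total <- total + log(col_lik)
  }
  total
}

random_aln <- function(tt, n_cols, seed, alpha = 1) {
  simulate_alignment(tt, n_cols, rate = 1, alpha_true = alpha,
                     model = "WAG", seed = seed)
}
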