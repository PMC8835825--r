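#' Default chain settings for the posterior sampler
#'
#' @param steps total Metropolis-Hastings steps.
#' @param thin record every `thin`-th post-burn-in state.
#' @param burnin_fraction fraction of steps discarded before recording.
#' @param move_weights named weights for the move mixture.
#' @param tuning named proposal window widths (log-scale for scalers).
#' @return list of chain settings.
#' @export
chain_settings <- function(steps = 20000, thin = 20, burnin_fraction = 0.1,
                           move_weights = c(tree_scale = 1, root_scale = 1,
                                            node_slide = 3, narrow_exchange = 3,
                                            wilson_balding = 2, alpha_scale = 1,
                                            lambda_scale = 1),
                           tuning = c(tree_scale = 0.2, root_scale = 0.5,
                                      alpha_scale = 0.5, lambda_scale = 0.7)) {
  if (all(move_weights <= 0)) abort_input("all move weights are zero")
  list(steps = steps, thin = thin, burnin_fraction = burnin_fraction,
       move_weights = move_weights[move_weights > 0], tuning = tuning)
}

# ---- proposal moves ------------------------------------------------------
# Each returns list(tt=, log_hastings=) or NULL for an immediate reject.

move_tree_scale <- function(tt, w) {
  s <- exp(runif(1, -w, w))
  internal <- which(tt$child1 > 0L)
  tt$height[internal] <- tt$height[internal] * s
  list(tt = tt, log_hastings = length(internal) * log(s))
}

move_root_scale <- function(tt, w) {
  r <- tt$root
  floor_h <- max(tt$height[c(tt$child1[r], tt$child2[r])])
  s <- exp(runif(1, -w, w))
  tt$height[r] <- floor_h + (tt$height[r] - floor_h) * s
  list(tt = tt, log_hastings = log(s))
}

move_node_slide <- function(tt) {
  internal <- setdiff(which(tt$child1 > 0L), tt$root)
  if (length(internal) == 0L) return(NULL)
  i <- internal[sample.int(length(internal), 1L)]
  lower <- max(tt$height[c(tt$child1[i], tt$child2[i])])
  upper <- tt$height[tt$parent[i]]
  tt$height[i] <- runif(1, lower, upper)
  list(tt = tt, log_hastings = 0)
}

move_narrow_exchange <- function(tt) {
  # p internal, not root, with grandparent g; swap a child of p with p's sibling
  elig <- which(tt$child1 > 0L & tt$parent > 0L)
  if (length(elig) == 0L) return(NULL)
  p <- elig[sample.int(length(elig), 1L)]
  g <- tt$parent[p]
  u <- if (tt$child1[g] == p) tt$child2[g] else tt$child1[g]
  if (tt$height[p] <= tt$height[u]) return(NULL)
  ch <- if (runif(1) < 0.5) tt$child1[p] else tt$child2[p]
  # swap ch <-> u
  if (tt$child1[p] == ch) tt$child1[p] <- u else tt$child2[p] <- u
  if (tt$child1[g] == u) tt$child1[g] <- ch else tt$child2[g] <- ch
  tt$parent[u] <- p
  tt$parent[ch] <- g
  list(tt = tt, log_hastings = 0)
}

subtree_nodes <- function(tt, i) {
  out <- i
  stack <- i
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- c(tt$child1[nd], tt$child2[nd])
    kids <- kids[kids > 0L]
    out <- c(out, kids)
    stack <- c(stack, kids)
  }
  out
}

move_wilson_balding <- function(tt) {
  # prune the subtree at i (parent p, not root) and regraft onto a random
  # edge at a uniform valid height; p is reused as the new attachment node
  n_all <- length(tt$parent)
  cand_i <- which(tt$parent > 0L & tt$parent != tt$root)
  if (length(cand_i) == 0L) return(NULL)
  i <- cand_i[sample.int(length(cand_i), 1L)]
  p <- tt$parent[i]
  g <- tt$parent[p]
  sib <- if (tt$child1[p] == i) tt$child2[p] else tt$child1[p]
  range_old <- tt$height[g] - max(tt$height[i], tt$height[sib])
  # detach p: sibling takes p's place under g
  if (tt$child1[g] == p) tt$child1[g] <- sib else tt$child2[g] <- sib
  tt$parent[sib] <- g
  # candidate targets: any non-root node outside subtree(i), excluding p
  sub <- subtree_nodes(tt, i)
  cand_j <- setdiff(which(tt$parent > 0L), c(sub, p))
  j <- cand_j[sample.int(length(cand_j), 1L)]
  pj <- tt$parent[j]
  lower <- max(tt$height[i], tt$height[j])
  range_new <- tt$height[pj] - lower
  if (range_new <= 0) return(NULL)
  # insert p on edge (pj, j)
  h_new <- runif(1, lower, tt$height[pj])
  if (tt$child1[pj] == j) tt$child1[pj] <- p else tt$child2[pj] <- p
  tt$parent[p] <- pj
  tt$child1[p] <- i
  tt$child2[p] <- j
  tt$parent[j] <- p
  tt$parent[i] <- p
  tt$height[p] <- h_new
  list(tt = tt, log_hastings = log(range_new) - log(range_old))
}

# ---- sampler -------------------------------------------------------------

#' Sample rooted time-trees and the gamma shape from the posterior
#'
#' Metropolis-Hastings over (topology, node heights, gamma shape alpha,
#' Yule birth rate lambda) under a strict clock with rate 1, so the root
#' height is in expected substitutions per site. The move mixture combines
#' whole-tree and root-height scalers, a uniform internal-node slide, a
#' narrow (NNI-like) exchange, a Wilson-Balding (SPR-like) regraft, and
#' multiplicative scalers for alpha and lambda.
#'
#' @param aln a [mosaic_msa()] with at least 3 taxa.
#' @param model a [substitution_model()]; its `alpha` is the chain's
#'   starting value.
#' @param chain settings from [chain_settings()].
#' @param seed integer seed; fixed seeds give identical runs.
#' @param likelihood set `FALSE` to force the likelihood to zero and sample
#'   from the prior (validity check).
#' @param start_tree optional [timetree()] initial state; default UPGMA.
#' @return A `mosaic_posterior`: `trees` (list of retained [timetree()]s),
#'   `trace` (tibble: state, posterior, likelihood, prior, treeHeight,
#'   gammaShape, lambda), `ess` (height and alpha), acceptance rates,
#'   settings and seed.
#' @export
sample_posterior <- function(aln, model, chain = chain_settings(), seed = 1,
                             likelihood = TRUE, start_tree = NULL) {
  if (n_taxa(aln) < 3L) abort_input("need at least 3 taxa")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  enc <- encode_alignment(aln)
  tt <- start_tree %||% upgma_start_tree(aln)
  tipdata <- pad_tipdata(enc, tt)   # tip order is invariant under the moves
  alpha <- model$alpha
  lambda <- 10
  mod <- model
  ll_fun <- function(tt, mod) {
    if (likelihood) loglik_padded(tt, tipdata, enc$weights, mod) else 0
  }
  ll <- ll_fun(tt, mod)
  lp <- log_prior(tt, alpha, lambda)

  wts <- chain$move_weights / sum(chain$move_weights)
  tun <- chain$tuning
  burnin <- floor(chain$steps * chain$burnin_fraction)
  keep_at <- seq(burnin + chain$thin, chain$steps, by = chain$thin)
  n_keep <- length(keep_at)
  trees <- vector("list", n_keep)
  trace <- matrix(NA_real_, n_keep, 7,
                  dimnames = list(NULL, c("state", "posterior", "likelihood",
                                          "prior", "treeHeight", "gammaShape",
                                          "lambda")))
  acc <- rej <- setNames(numeric(length(wts)), names(wts))
  ki <- 1L

  for (step in seq_len(chain$steps)) {
    mv <- sample(names(wts), 1L, prob = wts)
    new_alpha <- alpha
    new_lambda <- lambda
    prop <- switch(mv,
      tree_scale = move_tree_scale(tt, tun[["tree_scale"]]),
      root_scale = move_root_scale(tt, tun[["root_scale"]]),
      node_slide = move_node_slide(tt),
      narrow_exchange = move_narrow_exchange(tt),
      wilson_balding = move_wilson_balding(tt),
      alpha_scale = {
        u <- runif(1, -tun[["alpha_scale"]], tun[["alpha_scale"]])
        new_alpha <- alpha * exp(u)
        list(tt = tt, log_hastings = u)
      },
      lambda_scale = {
        u <- runif(1, -tun[["lambda_scale"]], tun[["lambda_scale"]])
        new_lambda <- lambda * exp(u)
        list(tt = tt, log_hastings = u)
      })
    ok <- FALSE
    if (!is.null(prop) && new_alpha > 1e-3 && new_alpha < 500 &&
        new_lambda > 1e-6 && new_lambda < 1e6) {
      new_mod <- mod
      if (new_alpha != alpha) {
        new_mod$alpha <- new_alpha
        new_mod$rates <- discrete_gamma_rates(new_alpha, mod$k)
      }
      new_lp <- log_prior(prop$tt, new_alpha, new_lambda)
      if (is.finite(new_lp)) {
        new_ll <- if (likelihood && (mv != "lambda_scale")) {
          ll_fun(prop$tt, new_mod)
        } else ll
        log_acc <- (new_ll + new_lp) - (ll + lp) + prop$log_hastings
        if (log(runif(1)) < log_acc) {
          tt <- prop$tt; alpha <- new_alpha; lambda <- new_lambda
          mod <- new_mod; ll <- new_ll; lp <- new_lp
          ok <- TRUE
        }
      }
    }
    if (ok) acc[mv] <- acc[mv] + 1 else rej[mv] <- rej[mv] + 1
    if (ki <= n_keep && step == keep_at[ki]) {
      trees[[ki]] <- tt
      trace[ki, ] <- c(step, ll + lp, ll, lp, tree_height(tt), alpha, lambda)
      ki <- ki + 1L
    }
  }
  trace <- as_tibble(as.data.frame(trace))
  structure(list(
    trees = trees,
    trace = trace,
    ess = c(height = ess(trace$treeHeight), alpha = ess(trace$gammaShape)),
    acceptance = acc / pmax(acc + rej, 1),
    chain = chain, seed = seed, model = model$name,
    likelihood_on = likelihood
  ), class = "mosaic_posterior")
}

#' @export
print.mosaic_posterior <- function(x, ...) {
  cat(sprintf("<mosaic_posterior: %d retained trees (%s), ESS height %.0f, alpha %.0f>\n",
              length(x$trees), x$model, x$ess["height"], x$ess["alpha"]))
  invisible(x)
}

#' Effective sample size via integrated autocorrelation time
#'
#' Geyer's initial positive-sequence truncation on the empirical
#' autocorrelations.
#'
#' @param x numeric chain.
#' @return estimated ESS.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || var(x) == 0) return(NA_real_)
  rho <- acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE)$acf[-1]
  tau <- 1
  for (m in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[m] + rho[m + 1]
    if (is.na(pair) || pair <= 0) break
    tau <- tau + 2 * pair
  }
  n / tau
}

#' Retained trees as an ape multiPhylo
#' @param post a `mosaic_posterior`.
#' @return `multiPhylo`.
#' @export
posterior_phylo <- function(post) {
  trees <- lapply(post$trees, timetree_to_phylo)
  class(trees) <- "multiPhylo"
  trees
}

#' Write the tree ensemble (NEXUS + Newick) and the trace log
#'
#' The NEXUS file carries a translate table (DensiTree/FigTree-compatible);
#' the trace is a BEAST-like tab-separated log.
#'
#' @param post a `mosaic_posterior`.
#' @param stem output path stem; writes `<stem>.trees` (NEXUS),
#'   `<stem>.nwk`, `<stem>.log`.
#' @return invisible character vector of the files written.
#' @export
write_posterior <- function(post, stem) {
  trees <- posterior_phylo(post)
  nexus <- paste0(stem, ".trees")
  nwk <- paste0(stem, ".nwk")
  logf <- paste0(stem, ".log")
  ape::write.nexus(trees, file = nexus, translate = TRUE)
  ape::write.tree(trees, file = nwk)
  utils::write.table(post$trace, logf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nexus, nwk, logf))
}
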