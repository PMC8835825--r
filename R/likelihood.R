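#' Encode an alignment as model-state integers with pattern compression
#'
#' @param aln a [mosaic_msa()].
#' @return list with `tipdata` (taxa x patterns, entries 0..19 or -1 for
#'   gap/unknown/ambiguous) and `weights` (pattern multiplicities).
#' @keywords internal
encode_alignment <- function(aln) {
  m <- unclass(aln)
  code <- matrix(match(m, AA_ALPHABET) - 1L, nrow(m), ncol(m))
  code[is.na(code)] <- -1L
  key <- apply(code, 2, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(tipdata = code[, first, drop = FALSE], weights = weights,
       taxa = rownames(m))
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Site-independent likelihood of the alignment on a rooted time-tree under
#' the model's reversible generator, averaging over the discrete-gamma
#' categories with equal weights. Gaps and unknowns are missing data.
#' Computed in compiled code with per-node scaling, so it stays finite for
#' hundreds of taxa.
#'
#' @param tt a [timetree()] whose tips match the alignment's taxa.
#' @param aln a [mosaic_msa()], or the result of `encode_alignment()`.
#' @param model a [substitution_model()].
#' @return log-likelihood (scalar).
#' @export
log_likelihood <- function(tt, aln, model) {
  enc <- if (inherits(aln, "mosaic_msa")) encode_alignment(aln) else aln
  if (!identical(sort(enc$taxa), sort(tt$tip_labels))) {
    abort_input("tree taxa and alignment taxa differ")
  }
  tipdata <- pad_tipdata(enc, tt)
  loglik_padded(tt, tipdata, enc$weights, model)
}

# tip rows reordered to the tree's labels, padded to 2n-1 node slots
pad_tipdata <- function(enc, tt) {
  tipdata <- enc$tipdata[match(tt$tip_labels, enc$taxa), , drop = FALSE]
  if (tt$n_tips > 1L) {
    tipdata <- rbind(tipdata, matrix(-1L, tt$n_tips - 1L, ncol(tipdata)))
  }
  tipdata
}

loglik_padded <- function(tt, tipdata, weights, model) {
  prune_loglik_cpp(tt$parent, tt$child1, tt$child2, tt$height,
                   tt$root, tt$n_tips, tipdata, weights,
                   model$eigvec, model$eigval, unname(model$freqs),
                   model$rates)
}

#' Log prior density of the sampler state
#'
#' Yule (pure-birth) prior on the time-tree,
#' `log p(T | lambda) = (n-1) log lambda - lambda * sum(internal heights)`,
#' with `lambda` under an exponential hyperprior (mean
#' `lambda_mean`), and an exponential(mean 1) prior on the gamma shape.
#'
#' @param tt a [timetree()].
#' @param alpha gamma shape value.
#' @param lambda Yule birth rate.
#' @param lambda_mean mean of the exponential hyperprior on `lambda`.
#' @return log prior density (scalar).
#' @export
log_prior <- function(tt, alpha, lambda, lambda_mean = 10) {
  if (alpha <= 0 || lambda <= 0) return(-Inf)
  internal <- which(tt$child1 > 0L)
  lp_tree <- (tt$n_tips - 1L) * log(lambda) - lambda * sum(tt$height[internal])
  lp_alpha <- -alpha                               # Exp(mean 1)
  lp_lambda <- -log(lambda_mean) - lambda / lambda_mean
  lp_tree + lp_alpha + lp_lambda
}
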