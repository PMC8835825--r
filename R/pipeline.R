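#' Compute all three phylogenetic metrics for a set of partitions
#'
#' Runs the posterior sampler on each partition sub-alignment, reduces the
#' ensembles to tree height, shape and clade support, computes the
#' conservation quality on the shared normalization of the full alignment,
#' and assembles design-matrix rows ready for regression.
#'
#' @param aln the full scaffold [mosaic_msa()].
#' @param masks named list of [partition_mask()].
#' @param clade_map tibble mapping taxa to clades.
#' @param model substitution model name (`"WAG"` or `"LG"`).
#' @param chain [chain_settings()] for the sampler.
#' @param seed integer seed; partition i runs with `seed + i`.
#' @param alpha0 starting gamma shape.
#' @return list: `design` (tibble, one row per mask; the support column is
#'   named `S_WAG` or `S_LG` after the model) and `support` (per-clade
#'   support tibbles, one per partition), `posteriors` (the
#'   `mosaic_posterior` objects).
#' @export
partition_metrics <- function(aln, masks, clade_map, model = "WAG",
                              chain = chain_settings(), seed = 1,
                              alpha0 = 1) {
  check_clade_map(clade_map, aln)
  mod <- substitution_model(model, alpha = alpha0)
  profile <- quality_profile(aln)
  supp_col <- paste0("S_", toupper(model))
  rows <- vector("list", length(masks))
  supports <- vector("list", length(masks))
  posteriors <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    mask <- masks[[i]]
    sub <- apply_partition(aln, mask)
    post <- sample_posterior(sub, mod, chain = chain, seed = seed + i)
    supp <- clade_support(post, clade_map)
    supp$partition <- mask$name
    qs <- partition_mean_quality(aln, mask, profile = profile)
    ms <- summarize_trace(post)
    row <- assemble_design_row(mask, q = qs$mean_q,
                               tree_height = ms$tree_height,
                               shape = ms$shape)
    row[[supp_col]] <- mean_support(supp)
    rows[[i]] <- row
    supports[[i]] <- supp
    posteriors[[i]] <- post
  }
  names(supports) <- names(posteriors) <- names(masks)
  list(design = dplyr::bind_rows(rows), support = dplyr::bind_rows(supports),
       posteriors = posteriors)
}
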