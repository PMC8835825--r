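test_that("fixed seeds give identical runs and traces match their trees", {
  bt <- simulate_base_tree(3, 3, seed = 5, base_height = 0.5)
  aln <- random_aln(bt$tree, 40, seed = 6)
  m <- substitution_model("WAG", alpha = 1, k = 4)
  ch <- chain_settings(steps = 400, thin = 10, burnin_fraction = 0.25)
  p1 <- sample_posterior(aln, m, ch, seed = 99)
  p2 <- sample_posterior(aln, m, ch, seed = 99)
  expect_equal(p1$trace, p2$trace)
  expect_equal(length(p1$trees), nrow(p1$trace))
  heights <- vapply(p1$trees, tree_height, numeric(1))
  expect_equal(heights, p1$trace$treeHeight)
  p3 <- sample_posterior(aln, m, ch, seed = 100)
  expect_false(isTRUE(all.equal(p1$trace$posterior, p3$trace$posterior)))
})

test_that("moves preserve time-tree invariants along a long random walk", {
  bt <- simulate_base_tree(4, 3, seed = 2, base_height = 0.7)
  aln <- random_aln(bt$tree, 10, seed = 3)
  m <- substitution_model("WAG", alpha = 1, k = 2)
  post <- sample_posterior(aln, m,
                           chain_settings(steps = 800, thin = 40,
                                          burnin_fraction = 0),
                           seed = 12, likelihood = FALSE)
  for (tt in post$trees) {
    expect_silent(mosaicphy:::validate_timetree(tt))
    expect_setequal(tt$tip_labels, bt$tree$tip_labels)
  }
})

test_that("zero-weight move mixtures are a config error", {
  expect_error(chain_settings(move_weights = c(node_slide = 0)), "zero")
})

test_that("sampler requires at least three taxa", {
  aln <- mosaic_msa(c(a = "AR", b = "AK"))
  m <- substitution_model("WAG", 1, 2)
  expect_error(sample_posterior(aln, m), "3 taxa")
})

test_that("ESS estimator is calibrated on iid and degenerate traces", {
  set.seed(31)
  x <- rnorm(1000)
  e <- ess(x)
  expect_gte(e, 500)
  expect_lte(e, 1500)
  expect_true(is.na(ess(rep(1, 100))))
  skip_if_not_installed("coda")
  e_ref <- unname(coda::effectiveSize(x))   # independent estimator
  expect_gte(e_ref, 500)
  expect_lte(e_ref, 1500)
})

test_that("trace summaries respect burn-in arithmetic and warn on low ESS", {
  tr <- tibble::tibble(treeHeight = rnorm(1000, 2), gammaShape = rnorm(1000, 1))
  s <- summarize_trace(tr, burnin_fraction = 0.1)
  expect_equal(s$n_used, 900)
  const <- tibble::tibble(treeHeight = rep(2, 50), gammaShape = rep(1, 50))
  expect_warning(s2 <- summarize_trace(const), "ESS")
  expect_equal(s2$tree_height, 2)
  expect_error(summarize_trace(tr[0, ]), "burn-in")
})

test_that("posterior ensembles round-trip through NEXUS and Newick with traces", {
  bt <- simulate_base_tree(3, 3, seed = 1, base_height = 0.5)
  aln <- random_aln(bt$tree, 20, seed = 2)
  m <- substitution_model("WAG", 1, 2)
  post <- sample_posterior(aln, m,
                           chain_settings(steps = 200, thin = 20,
                                          burnin_fraction = 0.1), seed = 3)
  stem <- tempfile()
  files <- write_posterior(post, stem)
  trees_nex <- read_tree_ensemble(paste0(stem, ".trees"))
  trees_nwk <- read_tree_ensemble(paste0(stem, ".nwk"))
  expect_length(trees_nex, length(post$trees))
  expect_length(trees_nwk, length(post$trees))
  expect_setequal(trees_nex[[1]]$tip.label, bt$tree$tip_labels)
  log <- read.delim(paste0(stem, ".log"))
  expect_equal(names(log), c("state", "posterior", "likelihood", "prior",
                             "treeHeight", "gammaShape", "lambda"))
  expect_equal(log$treeHeight, post$trace$treeHeight, tolerance = 1e-6)
  # BEAST-style bracketed comments are tolerated
  nwk2 <- tempfile(fileext = ".nwk")
  writeLines("((a:1[&rate=1],b:1):0.5[&rate=2],c:1.5);", nwk2)
  tr <- read_tree_ensemble(nwk2)
  expect_equal(sort(tr[[1]]$tip.label), c("a", "b", "c"))
})

test_that("posterior root height tracks the divergence the mutation rate produced", {
  # with a unit clock, tree height measures expected substitutions/site, so
  # a partition simulated at a lower rate yields a proportionally lower
  # posterior root height (the low-rate/low-height signature of the late
  # module in the reference design)
  m <- substitution_model("WAG", alpha = 1.5, k = 4)
  bt <- simulate_base_tree(3, 3, seed = 8, base_height = 0.5)
  ch <- chain_settings(steps = 2500, thin = 10, burnin_fraction = 0.3)
  heights <- vapply(c(0.3, 3), function(r) {
    aln <- simulate_alignment(bt$tree, 120, rate = r, alpha_true = 1.5,
                              model = "WAG", seed = 77)
    suppressWarnings(
      summarize_trace(sample_posterior(aln, m, ch, seed = 42))$tree_height)
  }, numeric(1))
  expect_gt(heights[2] / heights[1], 1.5)
})
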