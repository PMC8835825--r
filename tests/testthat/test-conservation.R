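pam <- read_substitution_matrix()

test_that("bundled PAM250 is the classic Dayhoff integer log-odds table", {
  expect_true(isSymmetric(pam))
  expect_equal(dim(pam), c(20, 20))
  expect_equal(range(pam), c(-8, 17))
  expect_equal(pam["W", "W"], 17)
  expect_equal(pam["A", "A"], 2)
})

test_that("identical-residue columns score 100 and gap columns are missing", {
  for (res in c("A", "W", "C")) {
    cq <- column_quality(rep(res, 6), pam, norm = 5)
    expect_equal(cq$q, 100)
    expect_equal(cq$dbar, 0)
  }
  cq <- column_quality(rep("-", 4), pam, norm = 5)
  expect_true(is.na(cq$q))
})

test_that("column quality matches the hand-computed consensus-distance value", {
  # frozen from an independent spreadsheet-style evaluation of the formula
  # for the column (A, A, V, L) under PAM250
  cq <- column_quality(c("A", "A", "V", "L"), pam)
  expect_equal(cq$dbar, 7.14804997123, tolerance = 1e-10)
  cq10 <- column_quality(c("A", "A", "V", "L"), pam, norm = 10)
  expect_equal(cq10$q, 100 * (1 - 7.14804997123 / 10), tolerance = 1e-9)
})

test_that("quality is invariant to row order and duplication of conserved rows", {
  col <- c("A", "V", "A", "L", "I")
  q1 <- column_quality(col, pam, norm = 10)$q
  q2 <- column_quality(rev(col), pam, norm = 10)$q
  expect_equal(q1, q2)
  cons <- rep("K", 5)
  expect_equal(column_quality(c(cons, "K"), pam, norm = 10)$q,
               column_quality(cons, pam, norm = 10)$q)
})

test_that("partition means use a common normalization and bracket the union", {
  aln <- mosaic_msa(c(s1 = "AAAACD", s2 = "AAAVCD", s3 = "AALVCE",
                      s4 = "AAIVCE"))
  prof <- quality_profile(aln)
  expect_true(all(prof$q >= 0 & prof$q <= 100, na.rm = TRUE))
  m_left <- partition_mask("left", 1:3)
  m_right <- partition_mask("right", 4:6)
  m_all <- partition_mask("all", 1:6)
  ql <- partition_mean_quality(aln, m_left, profile = prof)$mean_q
  qr <- partition_mean_quality(aln, m_right, profile = prof)$mean_q
  qa <- partition_mean_quality(aln, m_all, profile = prof)$mean_q
  expect_gte(qa, min(ql, qr))
  expect_lte(qa, max(ql, qr))
  expect_equal(partition_mean_quality(
    mosaic_msa(c(a = "R", b = "R")), partition_mask("one", 1))$mean_q, 100)
})

test_that("low-divergence partitions score higher mean quality than high-divergence ones", {
  ds <- generate_mosaic_dataset(
    mosaic_config(n_clades = 4, taxa_per_clade = 5,
                  partitions = tibble::tibble(
                    name = c("slow", "fast"), n_cols = c(40L, 40L),
                    rate = c(0.2, 3), alpha = c(1.5, 1.5),
                    transplants = c(0L, 0L))),
    seed = 9)
  prof <- quality_profile(ds$alignment)
  q_slow <- partition_mean_quality(ds$alignment, ds$masks$slow,
                                   profile = prof)$mean_q
  q_fast <- partition_mean_quality(ds$alignment, ds$masks$fast,
                                   profile = prof)$mean_q
  expect_gt(q_slow, q_fast)
})

test_that("partition quality correlates with the negative log shape across partitions", {
  # partitions differing only in simulated rate variance (alpha); the
  # conservation score and -log(alpha_true) should co-vary positively
  alphas <- c(0.3, 0.6, 1, 2, 4, 8)
  parts <- tibble::tibble(name = sprintf("p%d", seq_along(alphas)),
                          n_cols = 30L, rate = 1.2, alpha = alphas,
                          transplants = 0L)
  ds <- generate_mosaic_dataset(
    mosaic_config(n_clades = 4, taxa_per_clade = 5, partitions = parts),
    seed = 21)
  prof <- quality_profile(ds$alignment)
  qs <- vapply(parts$name, function(nm) {
    partition_mean_quality(ds$alignment, ds$masks[[nm]],
                           profile = prof)$mean_q
  }, numeric(1))
  expect_gt(cor(qs, -log(alphas)), 0)
})
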