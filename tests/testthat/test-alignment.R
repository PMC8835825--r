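test_that("FASTA round trip preserves sequences and parses clades", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">TrpRS_eco", "ACDEFGHIKL", ">TrpRS_bsu", "MNPQRSTVWY"), fa)
  res <- read_msa(fa)
  expect_s3_class(res$alignment, "mosaic_msa")
  expect_equal(ncol(res$alignment), 10)
  expect_equal(res$clade_map$clade, c("TrpRS", "TrpRS"))

  out <- tempfile(fileext = ".fasta")
  write_msa(res$alignment, out)
  again <- read_msa(out)
  expect_identical(unclass(again$alignment), unclass(res$alignment))
})

test_that("malformed alignments are rejected", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "MNPQRSTVW"), fa)
  expect_error(read_msa(fa), "ragged")

  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">a", "ACD"), fa2)
  expect_error(read_msa(fa2), "duplicate")

  fa3 <- tempfile(fileext = ".fasta")
  writeLines(character(0), fa3)
  expect_error(read_msa(fa3))
})

test_that("synthetic dataset yields the expected clade structure", {
  ds <- generate_mosaic_dataset(mosaic_config(n_clades = 10,
                                              taxa_per_clade = 20),
                                seed = 4)
  cm <- ds$clade_map
  expect_equal(nrow(cm), 200)
  expect_equal(length(unique(cm$clade)), 10)
  expect_true(all(table(cm$clade) == 20))
  expect_equal(ncol(ds$alignment), 103)
})

test_that("apply_partition selects columns and composes", {
  aln <- mosaic_msa(c(x = "ACDEFGHIKL", y = "ACDEFGHIKV"))
  full <- partition_mask("full", 1:10)
  expect_identical(unclass(apply_partition(aln, full)), unclass(aln))

  m1 <- partition_mask("m1", c(2, 3, 5, 7, 9))
  sub <- apply_partition(aln, m1)
  expect_equal(ncol(sub), 5)
  # composition of partitions: applying a sub-mask of the already-extracted
  # columns equals one application of the composed mask
  m2_rel <- partition_mask("m2", c(1, 4))           # within sub coordinates
  m2_abs <- partition_mask("m2", m1$columns[c(1, 4)])
  expect_identical(unclass(apply_partition(sub, m2_rel)),
                   unclass(apply_partition(aln, m2_abs)))

  expect_error(apply_partition(aln, partition_mask("bad", 11)), "range")
  expect_error(partition_mask("empty", integer(0)), "empty")
})

test_that("shipped partition config reproduces scaffold segment sizes", {
  cfg <- system.file("extdata", "scaffold_partitions.yaml",
                     package = "mosaicphy")
  masks <- read_partition_config(cfg)
  expect_equal(masks$urzyme$numb, 83)
  expect_equal(masks$CP1$numb, 20)
  expect_equal(masks$Full$numb, 103)
  expect_equal(masks$Protoz$numb, 46)
  expect_setequal(masks$Full$columns,
                  union(masks$urzyme$columns, masks$CP1$columns))
})

test_that("balanced subsets have 20 columns in disjoint 5-blocks inside the urzyme", {
  urz <- partition_mask("urzyme", 1:83)
  subsets <- sample_balanced_subsets(urz, seed = 42)
  expect_length(subsets, 7)
  for (s in subsets) {
    expect_equal(s$numb, 20)
    expect_true(all(s$columns %in% urz$columns))
    # columns decompose into exactly 4 runs of 5 consecutive indices
    runs <- split(s$columns, cumsum(c(1, diff(s$columns) != 1)))
    expect_true(all(lengths(runs) %% 5 == 0))
    expect_equal(sum(lengths(runs)), 20)
  }
  # determinism
  again <- sample_balanced_subsets(urz, seed = 42)
  expect_identical(lapply(subsets, `[[`, "columns"),
                   lapply(again, `[[`, "columns"))
  # degenerate: one block per subset
  one <- sample_balanced_subsets(urz, n_subsets = 2, block_len = 5,
                                 total = 5, seed = 1)
  for (s in one) expect_equal(diff(range(s$columns)), 4)
  expect_error(sample_balanced_subsets(partition_mask("tiny", 1:10)),
               "shorter")
})

test_that("design rows carry composition, indicators and missing metrics", {
  full <- partition_mask("Full", 1:103, c(A = 4, B = 3, C = 1, CP1 = 2))
  row <- assemble_design_row(full, s_wag = 0.9, s_lg = 0.86, q = 48.8,
                             tree_height = 3.69, shape = 1.17)
  expect_equal(row$NUMB, 103)
  expect_equal(unlist(row[c("A", "B", "C", "CP1")]),
               c(A = 4, B = 3, C = 1, CP1 = 2))
  expect_equal(row$urzyme, 1L)
  expect_equal(row$protozyme, 1L)

  cp1 <- partition_mask("CP1", 84:103, c(A = 0, B = 0, C = 0, CP1 = 2))
  row_cp1 <- assemble_design_row(cp1, s_wag = 0.34)
  expect_equal(row_cp1$urzyme, 0L)
  expect_equal(row_cp1$protozyme, 0L)
  expect_equal(row_cp1$NUMB, 20)
  expect_true(is.na(row_cp1$S_LG))     # absent, not zero

  proto <- partition_mask("Protoz", 1:46, c(A = 4, B = 0, C = 0, CP1 = 0))
  row_p <- assemble_design_row(proto)
  expect_equal(row_p$NUMB, 46)
  expect_equal(row_p$protozyme_n, 4)
})

test_that("reference design matrix matches NUMB additivity and exports in order", {
  d <- reference_design_matrix()
  expect_equal(nrow(d), 11)
  full <- d[d$Subset == "Full", ]
  expect_equal(full$NUMB,
               d$NUMB[d$Subset == "urzyme"] + d$NUMB[d$Subset == "CP1"])
  out <- tempfile(fileext = ".csv")
  write_design_matrix(d, out)
  back <- read.csv(out)
  expect_equal(names(back)[1:11],
               c("Subset", "S_WAG", "S_LG", "Q", "TreeHeight", "Shape",
                 "A", "B", "C", "CP1", "NUMB"))
  expect_equal(back$TreeHeight, d$TreeHeight)
})
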