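test_that("pairwise identity matches the closed cases", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  # alignment ACDE/ACD-: 3 identities over alignment length 4
  expect_equal(pairwise_identity("ACDE", "ACD"), 75)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  expect_error(pairwise_identity("", "ACD"), "non-empty")
})

test_that("identity is exactly symmetric and bounded on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    a <- paste(sample(AA20, sample(10:30, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(10:30, 1), TRUE), collapse = "")
    ab <- pairwise_identity(a, b)
    expect_identical(ab, pairwise_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 100)
  }
})

test_that("alignment scores agree with an independent Gotoh DP", {
  set.seed(7)
  for (i in 1:20) {
    a <- paste(sample(AA20, sample(5:15, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(5:15, 1), TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(Biostrings::score(aln), oracle_nw_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("shorter-sequence denominator mimics CD-HIT-style identity", {
  par <- identity_params(denominator = "shorter_sequence")
  expect_equal(pairwise_identity("ACDE", "ACD", par), 100)
})

test_that("homology reduction keeps one representative per tight cluster", {
  base <- paste(rep(c("A", "C", "D", "E", "F"), 4), collapse = "")
  mutated <- base
  substr(mutated, 3, 3) <- "W"  # 19/20 identity = 95%
  unrelated <- paste(rep(c("K", "R", "H", "M", "Y"), 4), collapse = "")
  ds <- plastid_dataset(c("s1", "s2", "s3"), c(base, mutated, unrelated))
  # oracle: brute-force identities pin the expected clusters
  expect_gte(pairwise_identity(base, mutated), 90)
  expect_lt(pairwise_identity(base, unrelated), 90)
  red <- homology_reduce(ds, threshold = 90)
  expect_setequal(red$id, c("s1", "s3"))
  # two identical sequences: one survives
  dup <- plastid_dataset(c("a", "b"), c(base, base))
  expect_identical(nrow(homology_reduce(dup, 90)), 1L)
  # threshold 100 with no exact duplicates: input unchanged
  expect_identical(homology_reduce(ds, 100)$id, ds$id)
})

test_that("reduction is idempotent and per-class when labels are present", {
  set.seed(3)
  ds <- random_family_dataset(4, 3, L = 40, mut = 0.05)
  ds$fine <- rep(c("N_S", "P_S"), each = 6)
  red1 <- homology_reduce(ds, 90)
  red2 <- homology_reduce(red1, 90)
  expect_identical(red1$id, red2$id)
})

test_that("partitioning honours cluster boundaries and the target fraction", {
  set.seed(11)
  # family of 5 mutually similar + 1 unrelated singleton
  fam <- random_family_dataset(1, 5, L = 40, mut = 0.1)
  lone <- paste(sample(AA20, 40, TRUE), collapse = "")
  ds <- plastid_dataset(c(fam$id, "lone"), c(fam$sequence, lone))
  p <- homology_partition(ds, threshold = 40, independent_fraction = 0.15)
  expect_identical(p$independent$id, "lone")
  expect_identical(nrow(p$train_test), 5L)
  # 20 mutually dissimilar records at fraction 0.15: 3 go independent
  ds20 <- random_family_dataset(20, 1, L = 50)
  p20 <- homology_partition(ds20, 40, 0.15)
  expect_identical(nrow(p20$independent), 3L)
  # threshold 0 joins everything into one cluster
  expect_error(homology_partition(ds20, 0, 0.15), "single")
})

test_that("mean cross-set identity averages brute-force pair identities", {
  a <- plastid_dataset(c("a1", "a2"),
                       c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLWWWWWWWWWW"))
  b <- plastid_dataset(c("b1", "b2"),
                       c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRVVVVV"))
  expected <- mean(c(
    pairwise_identity(a$sequence[1], b$sequence[1]),
    pairwise_identity(a$sequence[1], b$sequence[2]),
    pairwise_identity(a$sequence[2], b$sequence[1]),
    pairwise_identity(a$sequence[2], b$sequence[2])))
  expect_equal(unname(mean_cross_identity(a, b)["all"]), expected)
  # identical singletons and fully dissimilar singletons
  s1 <- plastid_dataset("x", "ACDEFGHIKL")
  expect_equal(unname(mean_cross_identity(s1, s1)["all"]), 100)
  expect_equal(unname(mean_cross_identity(
    plastid_dataset("x", "AAAAAAAAAA"),
    plastid_dataset("y", "CCCCCCCCCC"))["all"]), 0)
  # class missing from one side is NA, not zero
  a$fine <- c("N_S", "N_S"); b$fine <- c("P_S", "P_S")
  cls <- mean_cross_identity(a, b)
  expect_true(is.na(cls["N_S"]))
})
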