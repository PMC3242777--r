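test_that("protein identity counts matches over non-gap columns", {
  expect_equal(pairwise_protein_identity(strrep("A", 221), strrep("A", 221)),
               1.0)
  expect_equal(pairwise_protein_identity("MKLVAGHEDQ", "MKLVAGHEDW"), 0.9)
  expect_equal(pairwise_protein_identity("MK-V", "MKLV"), 1.0)  # gap skipped
  expect_error(pairwise_protein_identity("MKL", "MK"), "equal length")
})

test_that("protein identity is 1 iff sequences are identical", {
  set.seed(5)
  aa <- c("A", "C", "D", "E", "F", "G")
  for (i in 1:10) {
    x <- paste0(sample(aa, 30, replace = TRUE), collapse = "")
    y <- paste0(sample(aa, 30, replace = TRUE), collapse = "")
    id <- pairwise_protein_identity(x, y)
    expect_gte(id, 0); expect_lte(id, 1)
    expect_identical(id == 1, x == y)
  }
})

test_that("NG86 synonymous site counts match hand enumeration", {
  tabs <- branchsite:::ng86_tables()
  idx <- branchsite:::codon_table()$index
  # hand-counted: fraction of the 9 single changes that are synonymous
  expect_equal(tabs$syn_sites[idx["GGG"]], 1)        # 4-fold third position
  expect_equal(tabs$syn_sites[idx["TTT"]], 1 / 3)    # 2-fold
  expect_equal(tabs$syn_sites[idx["ATG"]], 0)        # Met, unique codon
  expect_equal(tabs$syn_sites[idx["TGG"]], 0)        # Trp (stops -> nonsyn)
  expect_equal(tabs$syn_sites[idx["CTA"]], 4 / 3)    # Leu: 4-fold + TTA
})

test_that("NG86 pathway averaging matches hand enumeration for CCT/CAA", {
  tabs <- branchsite:::ng86_tables()
  idx <- branchsite:::codon_table()$index
  # two pathways: via CAT (0 syn, 2 nonsyn) and via CCA (1 syn, 1 nonsyn)
  expect_equal(tabs$sd[idx["CCT"], idx["CAA"]], 0.5)
  expect_equal(tabs$nd[idx["CCT"], idx["CAA"]], 1.5)
})

test_that("ks_ng86 handles identity, single differences and saturation", {
  s <- strrep("GGGAAACCCTTT", 2)
  d0 <- ks_ng86(s, s)
  expect_equal(d0$ks, 0)
  expect_equal(d0$ka, 0)

  # one synonymous third-position change among three Gly codons:
  # S = 3, Sd = 1, ps = 1/3, JC-corrected ks = -3/4 log(1 - 4/9)
  d1 <- ks_ng86("GGGGGGGGG", "GGAGGGGGG")
  expect_equal(d1$ks, -0.75 * log(5 / 9), tolerance = 1e-10)
  expect_equal(d1$ka, 0)

  # a single two-fold codon pair saturates the correction (ps = 3 > 3/4)
  d2 <- ks_ng86("AAA", "AAG")
  expect_true(is.na(d2$ks))
  expect_true(d2$saturated[["ks"]])

  expect_error(ks_ng86("---", "AAA"), "no comparable")
})

test_that("ks_ng86 is symmetric and zero on identical sequences", {
  set.seed(11)
  for (i in 1:5) {
    x <- random_codon_seq(20)
    y <- random_codon_seq(20)
    dxy <- ks_ng86(x, y); dyx <- ks_ng86(y, x)
    expect_equal(dxy$ks, dyx$ks)
    expect_equal(dxy$ka, dyx$ka)
    expect_equal(ks_ng86(x, x)$ks, 0)
  }
})

test_that("pairwise divergence table covers all pairs", {
  aln <- toy_alignment(n_taxa = 4, n_codons = 30, seed = 9)
  tab <- pairwise_divergence_table(aln)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$ks >= 0 | is.na(tab$ks)))
})
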