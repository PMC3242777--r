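test_that("simulated alignments have the requested dimensions", {
  tmpl <- dataset_template()
  set.seed(91)
  tree <- codon_tree(ape::rtree(31, rooted = FALSE))
  model <- template_model(tmpl, "A1")
  tree <- set_foreground(tree, which(tree$phylo$edge[, 2] > 31)[1])
  sim <- simulate_alignment(tree, model, 257, seed = 92)
  expect_equal(length(sim$alignment$taxa), 31)
  expect_equal(sim$alignment$n_codons, 257)
  expect_equal(length(sim$true_classes), 257)
  expect_false(anyNA(sim$alignment$codes))  # no gaps in simulated data
  expect_error(simulate_alignment(tree, model, 0, seed = 1), "positive")
})

test_that("the same seed reproduces a replicate bit-identically", {
  tree <- small_tree()
  model <- template_model(small_template(), "A2")
  s1 <- simulate_alignment(tree, model, 40, seed = 1234)
  s2 <- simulate_alignment(tree, model, 40, seed = 1234)
  expect_identical(s1$alignment$codes, s2$alignment$codes)
  expect_identical(s1$true_classes, s2$true_classes)
  s3 <- simulate_alignment(tree, model, 40, seed = 1235)
  expect_false(identical(s1$alignment$codes, s3$alignment$codes))
})

test_that("empirical class frequencies match the mixture proportions", {
  tree <- small_tree()
  tmpl <- small_template()
  model <- template_model(tmpl, "A2")
  n <- 3000
  sim <- simulate_alignment(tree, model, n, seed = 95)
  props <- model$mixture$proportions
  counts <- table(factor(sim$true_classes,
                         levels = model$mixture$labels))
  for (k in seq_along(props)) {
    se <- sqrt(props[k] * (1 - props[k]) / n)
    expect_lt(abs(counts[[k]] / n - props[k]), 3 * se + 1e-9)
  }
})

test_that("neutral simulation yields ka/ks near 1 (NG86 cross-check)", {
  tree <- read_tree("(A:0.2,B:0.2);")
  freqs <- gambiae_like_codon_usage()
  model <- codon_model_spec(2, freqs, model_mixture("M0", list(omega = 1)))
  sim <- simulate_alignment(tree, model, 4000, seed = 96)
  seqs <- alignment_sequences(sim$alignment)
  d <- ks_ng86(seqs[[1]], seqs[[2]])
  expect_false(any(d$saturated))
  expect_equal(d$ka / d$ks, 1, tolerance = 0.15)
})

test_that("site columns are exchangeable for the likelihood", {
  sim <- small_a2_data()
  tree <- small_tree()
  model <- template_model(small_template(), "A1")
  lnl <- log_likelihood(sim$alignment, tree, model)
  set.seed(97)
  perm <- sample(sim$alignment$n_codons)
  shuffled <- sim$alignment
  shuffled$codes <- shuffled$codes[, perm]
  expect_equal(log_likelihood(shuffled, tree, model), lnl,
               tolerance = 1e-9)
})

test_that("write_replicate emits alignment plus class sidecar", {
  sim <- small_a2_data()
  prefix <- file.path(tempdir(), "rep1")
  write_replicate(sim, prefix)
  expect_true(file.exists(paste0(prefix, ".fasta")))
  classes <- utils::read.delim(paste0(prefix, ".classes.tsv"))
  expect_equal(nrow(classes), sim$alignment$n_codons)
  expect_setequal(unique(classes$class), unique(sim$true_classes))
})
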