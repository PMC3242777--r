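test_that("the codon usage table is a valid frozen distribution", {
  u <- gambiae_like_codon_usage()
  expect_length(u, 61)
  expect_equal(sum(u), 1, tolerance = 1e-9)
  expect_true(all(u > 0))
  expect_identical(names(u), sense_codons())
  # GC3 bias: G/C-ending codons carry more mass than A/T-ending ones
  third <- substr(names(u), 3, 3)
  expect_gt(sum(u[third %in% c("G", "C")]), 0.55)
})

test_that("calibrated trees have the right shape and one foreground flag", {
  tr <- small_tree()
  expect_equal(n_branches(tr), 2 * 6 - 3)
  expect_equal(sum(tr$foreground), 1)
  # the foreground branch is internal
  fg_child <- tr$phylo$edge[tr$foreground, 2]
  expect_gt(fg_child, length(tr$phylo$tip.label))
})

test_that("kS calibration matches the paralog and ortholog levels", {
  tmpl <- dataset_template(n_taxa = 10, n_codons = 150)
  tr <- gstall_like_tree(3, n_taxa = 10, template = tmpl,
                         calib_codons = 120)
  expect_equal(n_branches(tr), 17)
  expect_lt(abs(attr(tr, "ks_mean") - 1.6), 0.3)    # paralog pairs
  expect_lt(abs(attr(tr, "ks_within") - 1.1), 0.3)  # ortholog pairs
  # independent check on a fresh dataset simulated at full length
  sim <- make_dataset(tmpl, "A1", seed = 4, tree = tr)
  kt <- pairwise_divergence_table(sim$alignment)
  same <- sub("_.*$", "", kt$taxon_a) == sub("_.*$", "", kt$taxon_b)
  expect_lt(abs(mean(kt$ks[!same], na.rm = TRUE) - 1.6), 0.5)
  expect_lt(abs(mean(kt$ks[same], na.rm = TRUE) - 1.1), 0.5)
})

test_that("branch counts follow 2n-3 at the study sizes", {
  # kept cheap: topology only, no calibration
  set.seed(6)
  expect_equal(nrow(ape::rtree(31, rooted = FALSE)$edge), 59)
  expect_equal(nrow(ape::rtree(28, rooted = FALSE)$edge), 53)
  expect_error(gstall_like_tree(1, n_taxa = 3), ">= 4")
})

test_that("make_dataset is deterministic and honours the null", {
  tmpl <- small_template()
  tr <- small_tree()
  d1 <- make_dataset(tmpl, "A1", seed = 5, tree = tr)
  d2 <- make_dataset(tmpl, "A1", seed = 5, tree = tr)
  expect_identical(d1$alignment$codes, d2$alignment$codes)
  expect_equal(length(d1$alignment$taxa), 6)
  expect_equal(d1$alignment$n_codons, 60)
  # under A1 no site class carries foreground omega > 1
  mix <- d1$params$model$mixture
  expect_true(all(mix$omega_fg <= 1))
  # under A2 classes 2a/2b do
  d3 <- make_dataset(tmpl, "A2", seed = 5, tree = tr)
  expect_true(any(d3$params$model$mixture$omega_fg > 1))
})

test_that("template validation catches bad inputs", {
  expect_error(dataset_template(p0 = 0.9, p1 = 0.2), "proportions")
  expect_error(dataset_template(target_ks = c(mean = -1, sd = 0.1)),
               "target")
})
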