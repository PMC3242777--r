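test_that("two-taxon likelihood matches the closed form", {
  aln <- toy_alignment(n_taxa = 2, n_codons = 25, seed = 21)
  tree <- read_tree("(A:0.15,B:0.25);")
  freqs <- gambiae_like_codon_usage()
  mix <- model_mixture("M0", list(omega = 0.4))
  model <- codon_model_spec(2, freqs, mix)
  lnl <- log_likelihood(aln, tree, model)
  # reversibility collapses the pair to a single path of total length
  P <- expm_pmat(2, 0.4, freqs, 0.4)
  closed <- sum(log(freqs[aln$codes[1, ]] *
                      P[cbind(aln$codes[1, ], aln$codes[2, ])]))
  expect_equal(lnl, closed, tolerance = 1e-8)
})

test_that("pruning equals brute-force enumeration on 4-taxon instances", {
  set.seed(31)
  tree <- read_tree("((A:0.2,B:0.35):0.12,C:0.3,D:0.18);")
  for (rep in 1:3) {
    freqs <- stats::runif(61, 0.5, 2); freqs <- freqs / sum(freqs)
    kappa <- stats::runif(1, 1, 5); omega <- stats::runif(1, 0.05, 2)
    model <- codon_model_spec(kappa, freqs,
                              model_mixture("M0", list(omega = omega)))
    sim <- simulate_alignment(tree, model, 6, seed = 100 + rep)
    lnl <- log_likelihood(sim$alignment, tree, model)
    # brute force: sum over all 61^2 internal-node codon assignments
    phylo <- ape::reorder.phylo(tree$phylo, "postorder")
    P <- lapply(phylo$edge.length, function(t)
      expm_pmat(kappa, omega, freqs, t))
    codes <- sim$alignment$codes[match(phylo$tip.label,
                                       sim$alignment$taxa), ]
    internals <- sort(unique(phylo$edge[, 1]))
    root <- phylo$edge[nrow(phylo$edge), 1]
    brute <- 0
    for (s in seq_len(ncol(codes))) {
      tot <- 0
      for (x in 1:61) for (y in 1:61) {
        st <- rep(NA_integer_, 6)
        st[seq_len(4)] <- codes[, s]
        st[internals] <- c(x, y)
        p <- freqs[st[root]]
        for (e in seq_len(nrow(phylo$edge)))
          p <- p * P[[e]][st[phylo$edge[e, 1]], st[phylo$edge[e, 2]]]
        tot <- tot + p
      }
      brute <- brute + log(tot)
    }
    expect_equal(lnl, brute, tolerance = 1e-8)
  }
})

test_that("a one-class mixture equals the plain M0 likelihood", {
  sim <- small_a2_data()
  tree <- small_tree()
  freqs <- small_template()$codon_usage
  m0 <- codon_model_spec(2, freqs, model_mixture("M0", list(omega = 0.3)))
  deg <- codon_model_spec(2, freqs, site_class_mixture(c(1), 0.3, 0.3))
  expect_equal(log_likelihood(sim$alignment, tree, m0),
               log_likelihood(sim$alignment, tree, deg), tolerance = 1e-10)
})

test_that("likelihood is invariant to the unrooted representation", {
  sim <- small_a2_data()
  tree <- small_tree()
  freqs <- small_template()$codon_usage
  model <- codon_model_spec(2, freqs, model_mixture("M1a",
                                                    list(p0 = 0.7,
                                                         omega0 = 0.2)))
  lnl1 <- log_likelihood(sim$alignment, tree, model)
  # re-root at a different internal node and unroot again (pulley principle)
  ph2 <- ape::unroot(ape::root(tree$phylo, outgroup = tree$phylo$tip.label[3],
                               resolve.root = TRUE))
  lnl2 <- log_likelihood(sim$alignment, codon_tree(ph2), model)
  expect_equal(lnl1, lnl2, tolerance = 1e-8)
})

test_that("mixture likelihood matches the independent oracle (branch-site)", {
  sim <- small_a2_data()
  tree <- small_tree()
  freqs <- small_template()$codon_usage
  mix <- model_mixture("A2", list(p0 = 0.6, p1 = 0.25, omega0 = 0.15,
                                  omega2 = 6))
  model <- codon_model_spec(2.2, freqs, mix)
  lnl <- log_likelihood(sim$alignment, tree, model)
  mult_bg <- oracle_mults(2.2, freqs, mix$omega_bg, mix$proportions)
  mult_fg <- oracle_mults(2.2, freqs, mix$omega_fg, mix$proportions)
  classes <- data.frame(weight = mix$proportions,
                        omega_bg = mix$omega_bg, omega_fg = mix$omega_fg,
                        mult_bg = mult_bg, mult_fg = mult_fg)
  expect_equal(lnl, oracle_loglik(sim$alignment, tree, 2.2, freqs, classes),
               tolerance = 1e-7)
})

test_that("gaps are marginalized and errors are raised where required", {
  tree <- read_tree("(A:0.1,B:0.2,C:0.3);")
  aln <- codon_alignment(c(A = "ATG---GGG", B = "ATGCCCGGG",
                           C = "ATGCCAGGA"))
  freqs <- rep(1 / 61, 61)
  model <- codon_model_spec(2, freqs, model_mixture("M0", list(omega = 1)))
  lnl_gap <- log_likelihood(aln, tree, model, per_site = TRUE)
  expect_true(is.finite(lnl_gap$lnL))
  expect_equal(length(lnl_gap$site_loglik), 3)

  wrong <- codon_alignment(c(A = "ATG", B = "ATG", D = "ATG"))
  expect_error(log_likelihood(wrong, tree, model), "match")

  a2 <- codon_model_spec(2, freqs, model_mixture("A2",
        list(p0 = 0.7, p1 = 0.2, omega0 = 0.1, omega2 = 3)))
  expect_error(log_likelihood(aln, tree, a2), "foreground")
})
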