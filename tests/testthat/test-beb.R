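# BEB site posteriors: checked against a direct grid-summation oracle that
# uses the independent R pruning (dense matrix exponentials) and explicit
# loops over the prior grid.

fake_a2_fit <- function(tree, kappa, freqs, p0, p1, omega0, omega2) {
  structure(list(model = "A2", converged = TRUE, kappa = kappa,
                 frequencies = freqs,
                 mixture = model_mixture("A2", list(p0 = p0, p1 = p1,
                                                    omega0 = omega0,
                                                    omega2 = omega2)),
                 params = list(p0 = p0, p1 = p1, omega0 = omega0,
                               omega2 = omega2),
                 tree = tree), class = "codon_fit")
}

oracle_beb <- function(aln, fit, grid_n = 10) {
  tree <- fit$tree; kappa <- fit$kappa; freqs <- fit$frequencies
  fl <- oracle_flow(kappa, freqs)
  mixfit <- fit$mixture
  rbar_bg <- sum(mixfit$proportions * (fl["a"] + fl["b"] * mixfit$omega_bg))
  rbar_fg <- sum(mixfit$proportions * (fl["a"] + fl["b"] * mixfit$omega_fg))
  cls_lik <- function(w_bg, w_fg) {
    classes <- data.frame(weight = 1, omega_bg = w_bg, omega_fg = w_fg,
                          mult_bg = unname((fl["a"] + fl["b"] * w_bg) /
                                             rbar_bg),
                          mult_fg = unname((fl["a"] + fl["b"] * w_fg) /
                                             rbar_fg))
    oracle_loglik(aln, tree, kappa, freqs, classes,
                  per_site = TRUE)$class_site[1, ]
  }
  mid <- (2 * seq_len(grid_n) - 1) / (2 * grid_n)
  w0g <- mid; w2g <- 1 + 10 * mid
  pp <- expand.grid(p0 = mid, p1 = mid)
  pp <- pp[pp$p0 + pp$p1 < 1, ]
  S <- aln$n_codons
  L1 <- cls_lik(1, 1)
  L0 <- lapply(w0g, function(w) cls_lik(w, w))
  L2b <- lapply(w2g, function(w) cls_lik(1, w))
  L2a <- list()
  for (i in seq_along(w0g)) for (j in seq_along(w2g))
    L2a[[paste(i, j)]] <- cls_lik(w0g[i], w2g[j])
  logFs <- c(); combos <- list()
  for (i in seq_along(w0g)) for (j in seq_along(w2g))
    for (m in seq_len(nrow(pp))) {
      p0 <- pp$p0[m]; p1 <- pp$p1[m]; p2 <- 1 - p0 - p1
      w <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
      lmat <- rbind(L0[[i]], L1, L2a[[paste(i, j)]], L2b[[j]])
      f <- colSums(w * lmat)
      combos[[length(combos) + 1]] <- list(w = w, lmat = lmat, f = f)
      logFs <- c(logFs, sum(log(f)))
    }
  M <- max(logFs)
  num <- matrix(0, 4, S); den <- 0
  for (gidx in seq_along(combos)) {
    co <- combos[[gidx]]
    mass <- exp(logFs[gidx] - M)
    den <- den + mass
    num <- num + mass * sweep(co$w * co$lmat, 2, co$f, "/")
  }
  t(num / den)
}

test_that("BEB posteriors match the direct grid-summation oracle", {
  set.seed(71)
  phylo <- ape::rtree(5, rooted = FALSE)
  phylo$edge.length <- stats::runif(nrow(phylo$edge), 0.1, 0.5)
  tree <- codon_tree(phylo)
  tree <- set_foreground(tree, which(phylo$edge[, 2] > 5)[1])
  freqs <- gambiae_like_codon_usage()
  gen <- codon_model_spec(2, freqs,
                          model_mixture("A2", list(p0 = 0.6, p1 = 0.2,
                                                   omega0 = 0.1,
                                                   omega2 = 8)))
  sim <- simulate_alignment(tree, gen, 20, seed = 72)
  fit <- fake_a2_fit(tree, 2, freqs, p0 = 0.6, p1 = 0.2, omega0 = 0.1,
                     omega2 = 8)
  beb <- beb_site_posteriors(sim$alignment, tree, fit)
  oracle <- oracle_beb(sim$alignment, fit)
  expect_equal(unname(beb$site_posterior), unname(oracle),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowSums(beb$site_posterior),
               rep(1, sim$alignment$n_codons), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a site simulated under strong foreground selection stands out", {
  tree <- read_tree(
    "((A:0.2,B:0.2):0.15,(C:0.2,D:0.2)#1:0.5,(E:0.2,F:0.2):0.15);")
  freqs <- gambiae_like_codon_usage()
  # one codon evolved with foreground omega 10, the rest under omega 0.1
  bg <- simulate_alignment(tree, codon_model_spec(2, freqs,
          site_class_mixture(1, 0.1, 0.1)), 19, seed = 82)
  sel <- simulate_alignment(tree, codon_model_spec(2, freqs,
          site_class_mixture(1, 0.1, 10)), 1, seed = 83)
  seqs <- paste0(alignment_sequences(bg$alignment)[bg$alignment$taxa],
                 alignment_sequences(sel$alignment)[bg$alignment$taxa])
  names(seqs) <- bg$alignment$taxa
  aln <- codon_alignment(seqs)
  fit <- fake_a2_fit(tree, 2, freqs, p0 = 0.9, p1 = 0.05, omega0 = 0.1,
                     omega2 = 10)
  beb <- beb_site_posteriors(aln, tree, fit)
  expect_equal(which.max(beb$positive_posterior), 20L)
  expect_gt(beb$positive_posterior[20], max(beb$positive_posterior[1:19]))
})

test_that("invariant sites never reach the 0.95 threshold", {
  tree <- small_tree()
  freqs <- small_template()$codon_usage
  taxa <- tree$phylo$tip.label
  seqs <- stats::setNames(rep(strrep("ATGGGCAAA", 2), length(taxa)), taxa)
  aln <- codon_alignment(seqs)
  fit <- fake_a2_fit(tree, 2, freqs, p0 = 0.8, p1 = 0.15, omega0 = 0.1,
                     omega2 = 9)
  beb <- beb_site_posteriors(aln, tree, fit)
  expect_true(all(beb$positive_posterior < 0.95))
})

test_that("classify_sites partitions by threshold with nested tiers", {
  beb <- structure(list(positive_posterior = c(0.996, 0.97, 0.5)),
                   class = "beb_result")
  cls <- classify_sites(beb)
  expect_equal(cls$above_99, 1L)
  expect_equal(cls$between, 2L)
  expect_equal(cls$below, 3L)
  expect_true(all(cls$above_99 %in% cls$above_95))

  none <- structure(list(positive_posterior = rep(0, 5)),
                    class = "beb_result")
  cls0 <- classify_sites(none)
  expect_length(cls0$above_95, 0)
  expect_length(cls0$above_99, 0)
})

test_that("BEB refuses unconverged fits", {
  tree <- small_tree()
  fit <- fake_a2_fit(tree, 2, gambiae_like_codon_usage(), 0.8, 0.15, 0.1, 9)
  fit$converged <- FALSE
  aln <- small_a2_data()$alignment
  expect_error(beb_site_posteriors(aln, tree, fit), "converge")
})
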