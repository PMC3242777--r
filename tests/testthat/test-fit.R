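test_that("M0 fitting recovers the generating parameters", {
  set.seed(61)
  phylo <- ape::rtree(8, rooted = FALSE)
  phylo$edge.length <- stats::runif(nrow(phylo$edge), 0.05, 0.4)
  tree <- codon_tree(phylo)
  freqs <- gambiae_like_codon_usage()
  truth <- codon_model_spec(2, freqs, model_mixture("M0", list(omega = 0.3)))
  sim <- simulate_alignment(tree, truth, 500, seed = 62)
  fit <- fit_model(sim$alignment, tree, "M0", frequencies = freqs,
                   restarts = 1)
  expect_true(fit$converged)
  expect_equal(fit$params$omega, 0.3, tolerance = 0.1 / 0.3)  # within 0.1
  expect_equal(fit$kappa, 2, tolerance = 0.25)
  expect_equal(fit$n_free_params, 1)
})

test_that("optimized lnL respects model nesting (M7 <= M8a <= M8)", {
  sim <- small_a2_data()
  tree <- small_tree()
  freqs <- codon_frequencies(sim$alignment, "F3x4")
  m7 <- fit_model(sim$alignment, tree, "M7", frequencies = freqs,
                  restarts = 1)
  m8a <- fit_model(sim$alignment, m7$tree, "M8a", frequencies = freqs,
                   restarts = 1,
                   init = list(kappa = m7$kappa, p0 = 0.95,
                               p = m7$params$p, q = m7$params$q))
  m8 <- fit_model(sim$alignment, m8a$tree, "M8", frequencies = freqs,
                  restarts = 1,
                  init = list(kappa = m8a$kappa, p0 = m8a$params$p0,
                              p = m8a$params$p, q = m8a$params$q,
                              omega_s = 1 + 1e-4))
  expect_gte(m8$lnL, m8a$lnL - 1e-4)
  expect_gte(m8a$lnL, m7$lnL - 1e-4)
  expect_equal(m7$n_free_params, 2)
  expect_equal(m8a$n_free_params, 3)
  expect_equal(m8$n_free_params, 4)
})

test_that("branch-site fits respect nesting and recover selection", {
  sim <- small_a2_data()  # generated under A2 with omega2 = 10
  tree <- small_tree()
  freqs <- codon_frequencies(sim$alignment, "F3x4")
  a1 <- fit_model(sim$alignment, tree, "A1", frequencies = freqs,
                  restarts = 1, init = list(p0 = 0.75, p1 = 0.2,
                                            omega0 = 0.1))
  a2 <- fit_model(sim$alignment, a1$tree, "A2", frequencies = freqs,
                  restarts = 1, fix_branch_lengths = TRUE,
                  fix_kappa = a1$kappa,
                  init = list(p0 = a1$params$p0, p1 = a1$params$p1,
                              omega0 = a1$params$omega0, omega2 = 2))
  expect_gte(a2$lnL, a1$lnL - 1e-6)
  expect_gte(a2$params$omega2, 1)
  expect_equal(a1$n_free_params, 3)
  expect_equal(a2$n_free_params, 4)
})

test_that("restart bookkeeping and failure flags are reported", {
  sim <- small_a2_data()
  tree <- small_tree()
  fit <- fit_model(sim$alignment, tree, "M0", restarts = 2, maxit = 60)
  expect_equal(nrow(fit$convergence), 2)
  expect_true(all(is.finite(fit$convergence$lnL)))
  expect_gte(fit$restart_spread, 0)
})

test_that("branch models require foreground flags where meaningful", {
  sim <- small_a2_data()
  phylo_noflag <- small_tree()$phylo
  bare <- codon_tree(phylo_noflag)
  expect_error(fit_model(sim$alignment, bare, "A2"), "foreground")
  expect_error(fit_model(sim$alignment, bare, "branch2_strict"),
               "foreground")
})

test_that("per-branch dN/dS report ranks branches", {
  sim <- small_a2_data()
  tree <- small_tree()
  fit <- fit_model(sim$alignment, tree, "branch2_strict", restarts = 1)
  tab <- branch_dn_ds(fit)
  expect_equal(nrow(tab), n_branches(tree))
  expect_true(all(tab$dN >= 0) && all(tab$dS >= 0))
  expect_equal(sort(unique(tab$omega)), sort(unique(c(fit$params$omega_bg,
                                                      fit$params$omega_fg))))
  expect_equal(min(tab$dN_rank), 1)
  # omega = dN/dS is recovered by the site-count conversion
  nz <- tab$dS > 1e-8
  expect_equal(tab$dN[nz] / tab$dS[nz], tab$omega[nz], tolerance = 1e-6)
})
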