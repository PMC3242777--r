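# Bayes Empirical Bayes identification of positively selected sites under
# branch-site model A. The mixture parameters (p0, p1, omega0, omega2) are
# integrated over a discrete prior grid while kappa, branch lengths and
# codon frequencies stay fixed at their maximum-likelihood estimates; the
# per-site posterior of the positively selected classes (2a + 2b) is the
# reported evidence for selection at that site.

# grid resolution per dimension; a documented constant so it can be varied
BEB_GRID_N <- 10

# prior grids: omega0 on (0,1), omega2 on (1,11) (midpoint categories);
# (p0, p1) uniform over the midpoint pairs inside the simplex
beb_grid <- function(n = BEB_GRID_N) {
  mid <- (2 * seq_len(n) - 1) / (2 * n)
  w0 <- mid
  w2 <- 1 + 10 * mid
  pp <- expand.grid(p0 = mid, p1 = mid)
  pp <- pp[pp$p0 + pp$p1 < 1, ]
  list(w0 = w0, w2 = w2, props = pp)
}

#' Bayes Empirical Bayes site posteriors under branch-site model A
#'
#' @param aln A [codon_alignment()].
#' @param tree A [codon_tree()] with the foreground branch flagged. The
#'   fitted tree stored in `a2_fit` is used for branch lengths.
#' @param a2_fit A converged `codon_fit` of model `A2` (model `A1` is also
#'   accepted, e.g. for null calibration).
#' @param grid_n Prior categories per dimension (default 10).
#' @return Object of class `beb_result`: `site_posterior` (sites x 4 matrix
#'   of class posteriors, classes 0, 1, 2a, 2b), `positive_posterior`
#'   (per-site P(2a) + P(2b)), `mean_omega_fg` (posterior mean foreground
#'   omega per site), and `flagged` (list of site indices above 0.95 and
#'   0.99).
#' @export
beb_site_posteriors <- function(aln, tree, a2_fit, grid_n = BEB_GRID_N) {
  if (!inherits(a2_fit, "codon_fit") || !(a2_fit$model %in% c("A1", "A2")))
    stop("a2_fit must be a branch-site (A1/A2) model fit")
  if (!a2_fit$converged)
    stop("branch-site fit did not converge; refit before running BEB")
  if (!is.null(tree) && !setequal(tree$phylo$tip.label,
                                  a2_fit$tree$phylo$tip.label))
    stop("tree does not match the fitted tree")
  ctx <- lik_context(aln, a2_fit$tree)  # fitted branch lengths
  if (!any(ctx$foreground)) stop("no foreground branch flagged")
  g <- beb_grid(grid_n)
  S <- ctx$n_sites
  kappa <- a2_fit$kappa
  freqs <- a2_fit$frequencies

  n0 <- length(g$w0); n2 <- length(g$w2)
  npat <- length(ctx$pattern_weights)
  # class rate multipliers stay fixed at the maximum-likelihood mixture
  # scaling (branch lengths keep the meaning they had in the fit)
  fl <- codon_flow(kappa, freqs)
  fitmix <- a2_fit$mixture
  rbar_bg <- sum(fitmix$proportions * (fl["a"] + fl["b"] * fitmix$omega_bg))
  rbar_fg <- sum(fitmix$proportions * (fl["a"] + fl["b"] * fitmix$omega_fg))
  cls_loglik <- function(w_bg, w_fg) {
    mult <- ifelse(ctx$foreground, (fl["a"] + fl["b"] * w_fg) / rbar_fg,
                   (fl["a"] + fl["b"] * w_bg) / rbar_bg)
    ctx_loglik(ctx, kappa, freqs, site_class_mixture(1, w_bg, w_fg),
               rate_mult = matrix(mult, ncol = 1))$classSiteLoglik[1, ]
  }
  # per-class site log-likelihood tables over the omega grid:
  # class 0: depends on w0; class 1: constant; class 2a: (w0, w2); 2b: w2
  l_class1 <- cls_loglik(1, 1)
  l_class0 <- matrix(0, n0, npat)
  l_class2a <- array(0, c(n0, n2, npat))
  l_class2b <- matrix(0, n2, npat)
  for (i in seq_len(n0))
    l_class0[i, ] <- cls_loglik(g$w0[i], g$w0[i])
  for (j in seq_len(n2)) {
    l_class2b[j, ] <- cls_loglik(1, g$w2[j])
    for (i in seq_len(n0))
      l_class2a[i, j, ] <- cls_loglik(g$w0[i], g$w2[j])
  }

  npp <- nrow(g$props)
  G <- npp * n0 * n2
  log_prior <- -log(G)
  # accumulate, per site pattern and class, the posterior mass
  post_num <- matrix(0, 4, npat)   # unnormalized, scaled by exp(-shift)
  mean_w_num <- numeric(npat)
  log_marg <- -Inf                  # log sum over grid of prior * lik(data)
  # first pass: compute log F_g for all grid points to get a stable shift
  logF <- numeric(G)
  wts <- ctx$pattern_weights
  # class weight matrix: 4 x npp, one column per (p0, p1) grid point
  p0v <- g$props$p0; p1v <- g$props$p1; p2v <- 1 - p0v - p1v
  wcls_mat <- rbind(p0v, p1v, p2v * p0v / (p0v + p1v),
                    p2v * p1v / (p0v + p1v))
  widx <- 1L
  elmat_store <- vector("list", n0 * n2)
  mxsum_store <- numeric(n0 * n2)
  mx_store <- vector("list", n0 * n2)
  ij <- 1L
  for (i in seq_len(n0)) for (j in seq_len(n2)) {
    lmat <- rbind(l_class0[i, ], l_class1, l_class2a[i, j, ], l_class2b[j, ])
    mx <- apply(lmat, 2, max)
    elmat <- exp(sweep(lmat, 2, mx))                # 4 x npat, max-shifted
    fs_all <- crossprod(elmat, wcls_mat)            # npat x npp
    logF[widx + seq_len(npp) - 1L] <-
      colSums(wts * log(fs_all)) + sum(wts * mx)
    elmat_store[[ij]] <- elmat
    mx_store[[ij]] <- mx
    widx <- widx + npp
    ij <- ij + 1L
  }
  shift <- max(logF)
  widx <- 1L
  ij <- 1L
  for (i in seq_len(n0)) for (j in seq_len(n2)) {
    elmat <- elmat_store[[ij]]
    w_fg <- c(g$w0[i], 1, g$w2[j], g$w2[j])
    for (m in seq_len(npp)) {
      wcls <- wcls_mat[, m]
      condk <- wcls * elmat                          # 4 x npat
      fs <- colSums(condk)
      gmass <- exp(logF[widx] - shift + log_prior)
      if (gmass > 0) {
        postk <- sweep(condk, 2, fs, "/")            # class posterior | g
        post_num <- post_num + gmass * postk
        mean_w_num <- mean_w_num + gmass * colSums(w_fg * postk)
      }
      widx <- widx + 1L
    }
    ij <- ij + 1L
  }
  tot <- colSums(post_num)
  site_post_pat <- t(sweep(post_num, 2, tot, "/"))
  mean_w_pat <- mean_w_num / tot
  map <- ctx$pattern_of_site
  site_posterior <- site_post_pat[map, , drop = FALSE]
  colnames(site_posterior) <- c("0", "1", "2a", "2b")
  positive <- site_posterior[, "2a"] + site_posterior[, "2b"]
  structure(list(
    site_posterior = site_posterior,
    positive_posterior = positive,
    mean_omega_fg = mean_w_pat[map],
    flagged = list(p95 = which(positive > 0.95), p99 = which(positive > 0.99)),
    grid_n = grid_n
  ), class = "beb_result")
}

#' Partition sites by BEB posterior thresholds
#'
#' @param beb A `beb_result`.
#' @param thresholds Two thresholds, default `c(0.95, 0.99)`.
#' @return List with `above_99` (P > 0.99), `between` (0.95 < P <= 0.99)
#'   and `below`, plus `above_95` (the union of the first two).
#' @export
classify_sites <- function(beb, thresholds = c(0.95, 0.99)) {
  lo <- min(thresholds); hi <- max(thresholds)
  p <- beb$positive_posterior
  list(above_99 = which(p > hi),
       between = which(p > lo & p <= hi),
       below = which(p <= lo),
       above_95 = which(p > lo))
}

#' Write a BEB site-posterior table to TSV
#' @param beb A `beb_result`.
#' @param path Output path.
#' @export
write_beb_table <- function(beb, path) {
  cls <- classify_sites(beb)
  tier <- rep("-", length(beb$positive_posterior))
  tier[cls$between] <- "P>0.95"
  tier[cls$above_99] <- "P>0.99"
  df <- data.frame(site = seq_along(beb$positive_posterior),
                   round(beb$site_posterior, 6),
                   positive = round(beb$positive_posterior, 6),
                   mean_omega_fg = round(beb$mean_omega_fg, 4),
                   tier = tier, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
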