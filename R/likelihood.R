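# Phylogenetic likelihood of a codon alignment under a site-class mixture.
# The pruning recursion runs in compiled code; this file builds the
# computational context (postorder edges, tip states, site patterns) and
# translates mixtures into per-class, per-edge omega assignments.

# Build the reusable computational context for one alignment + tree.
# Site columns are compressed to unique patterns with weights.
lik_context <- function(aln, tree) {
  check_taxa(aln, tree)
  phylo <- tree$phylo
  po <- ape::reorder.phylo(phylo, "postorder")
  key_orig <- paste(phylo$edge[, 1], phylo$edge[, 2])
  key_po <- paste(po$edge[, 1], po$edge[, 2])
  perm <- match(key_po, key_orig)
  foreground <- tree$foreground[perm]
  tip_codes <- aln$codes[match(po$tip.label, aln$taxa), , drop = FALSE]
  pat_key <- apply(tip_codes, 2, function(col) paste(col, collapse = ","))
  upat <- !duplicated(pat_key)
  pattern_of_site <- match(pat_key, pat_key[upat])
  tipStates <- tip_codes[, upat, drop = FALSE]
  weights <- as.numeric(tabulate(pattern_of_site, nbins = sum(upat)))
  list(edge = po$edge, edge_length = po$edge.length,
       foreground = foreground, tipStates = tipStates,
       pattern_weights = weights, pattern_of_site = pattern_of_site,
       n_sites = aln$n_codons, n_edges = nrow(po$edge),
       pair_type = codon_pair_type())
}

# Per-class, per-edge omega index matrix from a mixture (or an explicit
# per-edge omega vector for the free-ratio branch model).
omega_layout <- function(ctx, mixture, per_branch_omega = NULL) {
  if (!is.null(per_branch_omega)) {
    omegas <- unique(per_branch_omega)
    idx <- matrix(match(per_branch_omega, omegas), ncol = 1)
    return(list(omegas = omegas, omega_idx = idx,
                weights = 1))
  }
  k <- length(mixture$proportions)
  needs_fg <- any(mixture$omega_fg != mixture$omega_bg)
  if (needs_fg && !any(ctx$foreground))
    stop("model distinguishes foreground omega but no branch is flagged ",
         "foreground ('#1')")
  omegas <- unique(c(mixture$omega_bg, mixture$omega_fg))
  idx <- matrix(0L, ctx$n_edges, k)
  for (j in seq_len(k)) {
    idx[, j] <- match(mixture$omega_bg[j], omegas)
    idx[ctx$foreground, j] <- match(mixture$omega_fg[j], omegas)
  }
  list(omegas = omegas, omega_idx = idx, weights = mixture$proportions)
}

# Raw synonymous (a) and nonsynonymous-at-omega-1 (b) substitution flows of
# the unnormalized exchangeability; the substitution rate of a class with
# ratio omega is a + omega * b, which sets the class rate multipliers under
# mixture-average branch-length scaling (the convention of the standard ML
# codon software: a branch length is the expected number of substitutions
# per codon averaged over site classes).
codon_flow <- function(kappa, frequencies) {
  type <- codon_pair_type()
  Sk <- kappa * (type == 1L) + (type == 2L)
  Nk <- kappa * (type == 3L) + (type == 4L)
  pp <- outer(frequencies, frequencies)
  c(a = sum(Sk * pp), b = sum(Nk * pp))
}

# class-by-edge rate multipliers R(omega_ek) / mean_k R(omega_ek)
class_rate_mult <- function(ctx, lay, kappa, frequencies,
                            norm_weights = lay$weights) {
  fl <- codon_flow(kappa, frequencies)
  Rmat <- fl["a"] + fl["b"] * matrix(lay$omegas[lay$omega_idx],
                                     nrow = nrow(lay$omega_idx))
  Rbar <- as.vector(Rmat %*% norm_weights)
  Rmat / Rbar
}

# Core evaluation. Returns the cpp_pruning() result (lnL is pattern-weighted)
ctx_loglik <- function(ctx, kappa, frequencies, mixture,
                       edge_length = ctx$edge_length,
                       per_branch_omega = NULL, gradient = FALSE,
                       rate_mult = NULL) {
  lay <- omega_layout(ctx, mixture, per_branch_omega)
  if (is.null(rate_mult)) {
    rate_mult <- if (is.null(per_branch_omega))
      class_rate_mult(ctx, lay, kappa, frequencies)
    else matrix(1, ctx$n_edges, 1)
  }
  cpp_pruning(ctx$tipStates, ctx$edge, edge_length, lay$omega_idx,
              rate_mult, lay$omegas, kappa, frequencies, ctx$pair_type,
              lay$weights, ctx$pattern_weights, gradient)
}

#' Log-likelihood of an alignment and tree under a codon model
#'
#' Per-site likelihoods are mixtures over site classes, each class using its
#' foreground omega on flagged branches and background omega elsewhere;
#' gap/ambiguous codons are marginalized. Site log-likelihoods are summed.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [codon_tree()] whose leaves match the alignment taxa.
#' @param model A [codon_model_spec()].
#' @param per_site If `TRUE`, also return the per-site log-likelihoods.
#' @return The log-likelihood (numeric scalar), or a list with `lnL` and
#'   `site_loglik` when `per_site = TRUE`.
#' @export
log_likelihood <- function(aln, tree, model, per_site = FALSE) {
  ctx <- lik_context(aln, tree)
  res <- ctx_loglik(ctx, model$kappa, model$frequencies, model$mixture)
  if (!per_site) return(res$lnL)
  list(lnL = res$lnL, site_loglik = res$siteLoglik[ctx$pattern_of_site])
}
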