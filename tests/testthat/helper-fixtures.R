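# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's pruning core: transition probabilities come from a dense
# matrix exponential (Matrix::expm) and likelihoods from explicit
# recursion/enumeration in R, so implementation and check are independent.

random_codon_seq <- function(n, freqs = rep(1 / 61, 61)) {
  paste0(sense_codons()[sample.int(61, n, replace = TRUE, prob = freqs)],
         collapse = "")
}

toy_alignment <- function(n_taxa = 4, n_codons = 10, seed = 1,
                          labels = LETTERS[seq_len(n_taxa)]) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_taxa), function(i) random_codon_seq(n_codons), "")
  names(seqs) <- labels
  codon_alignment(seqs)
}

# dense matrix-exponential transition probabilities (independent of the
# eigendecomposition route used by the package)
expm_pmat <- function(kappa, omega, freqs, t) {
  Q <- build_rate_matrix(kappa, omega, freqs)
  as.matrix(Matrix::expm(Q * t))
}

# independent pruning in plain R over explicit per-edge, per-class omega
# and rate-multiplier assignments; classes: data.frame(weight, omega_bg,
# omega_fg, mult_bg, mult_fg)
oracle_loglik <- function(aln, tree, kappa, freqs, classes,
                          per_site = FALSE) {
  phylo <- ape::reorder.phylo(tree$phylo, "postorder")
  key0 <- paste(tree$phylo$edge[, 1], tree$phylo$edge[, 2])
  keyp <- paste(phylo$edge[, 1], phylo$edge[, 2])
  fg <- tree$foreground[match(keyp, key0)]
  ntip <- length(phylo$tip.label)
  codes <- aln$codes[match(phylo$tip.label, aln$taxa), , drop = FALSE]
  S <- ncol(codes)
  root <- phylo$edge[nrow(phylo$edge), 1]
  sitelik <- matrix(0, nrow(classes), S)
  for (k in seq_len(nrow(classes))) {
    P <- lapply(seq_len(nrow(phylo$edge)), function(e) {
      w <- if (fg[e]) classes$omega_fg[k] else classes$omega_bg[k]
      m <- if (fg[e]) classes$mult_fg[k] else classes$mult_bg[k]
      expm_pmat(kappa, w, freqs, phylo$edge.length[e] * m)
    })
    part <- matrix(1, 61, phylo$Nnode + ntip)
    partials <- vector("list", phylo$Nnode + ntip)
    for (i in seq_len(ntip)) {
      m <- matrix(0, 61, S)
      for (s in seq_len(S)) {
        if (is.na(codes[i, s])) m[, s] <- 1 else m[codes[i, s], s] <- 1
      }
      partials[[i]] <- m
    }
    for (e in seq_len(nrow(phylo$edge))) {
      par <- phylo$edge[e, 1]; ch <- phylo$edge[e, 2]
      if (is.null(partials[[par]])) partials[[par]] <- matrix(1, 61, S)
      partials[[par]] <- partials[[par]] * (P[[e]] %*% partials[[ch]])
    }
    sitelik[k, ] <- as.vector(freqs %*% partials[[root]])
  }
  persite <- log(colSums(classes$weight * sitelik))
  if (per_site) return(list(lnL = sum(persite), site = persite,
                            class_site = sitelik))
  sum(persite)
}

# synonymous / nonsynonymous substitution flows, recomputed from the
# genetic code by explicit enumeration
oracle_flow <- function(kappa, freqs) {
  type_tab <- outer(sense_codons(), sense_codons(),
                    Vectorize(function(a, b) {
    if (a == b) return(0L)
    sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
    d <- which(sa != sb)
    if (length(d) != 1) return(0L)
    ts <- paste(sort(c(sa[d], sb[d])), collapse = "") %in% c("AG", "CT")
    aa <- Biostrings::GENETIC_CODE[c(a, b)]
    syn <- aa[1] == aa[2]
    if (syn) (if (ts) 1L else 2L) else (if (ts) 3L else 4L)
  }))
  pp <- outer(freqs, freqs)
  c(a = sum(pp * (kappa * (type_tab == 1) + (type_tab == 2))),
    b = sum(pp * (kappa * (type_tab == 3) + (type_tab == 4))))
}

# rate multipliers matching the package's mixture-average scaling
oracle_mults <- function(kappa, freqs, omegas, weights) {
  fl <- oracle_flow(kappa, freqs)
  r <- fl["a"] + fl["b"] * omegas
  unname(r / sum(weights * r))
}

# small cached objects shared across test files
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_template <- function() dataset_template(n_taxa = 6, n_codons = 60)

small_tree <- function() fixture("small_tree", function() {
  gstall_like_tree(7, n_taxa = 6, template = small_template(),
                   calib_codons = 90)
})

small_a2_data <- function() fixture("small_a2_data", function() {
  tmpl <- small_template()
  tmpl$omega2 <- 10
  make_dataset(tmpl, "A2", seed = 13, tree = small_tree())
})
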