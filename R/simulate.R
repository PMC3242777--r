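# Evolver-style simulation of codon alignments along a tree. Each site
# draws a class from the mixture; the root codon is drawn from the
# stationary frequencies; every branch evolves by direct sampling from the
# exact transition matrix P(t) built with that class's branch-appropriate
# omega. Simulated alignments contain no gaps.

#' Simulate a codon alignment under a codon model
#'
#' @param tree A [codon_tree()]; foreground flags are honoured by mixtures
#'   whose foreground omegas differ.
#' @param model A [codon_model_spec()].
#' @param n_codons Number of codon sites (`> 0`).
#' @param seed Integer seed; the same seed reproduces the replicate
#'   bit-identically.
#' @return Object of class `sim_replicate`: `alignment`
#'   (a [codon_alignment()]), `true_classes` (per-site class labels from the
#'   mixture), `params` (generating model and tree) and `seed`.
#' @export
simulate_alignment <- function(tree, model, n_codons, seed = NULL) {
  if (!is.numeric(n_codons) || n_codons <= 0)
    stop("n_codons must be a positive count")
  n_codons <- as.integer(n_codons)
  mix <- model$mixture
  needs_fg <- any(mix$omega_fg != mix$omega_bg)
  if (needs_fg && !any(tree$foreground))
    stop("mixture distinguishes foreground omega but no branch is flagged")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  phylo <- ape::reorder.phylo(tree$phylo, "postorder")
  key_orig <- paste(tree$phylo$edge[, 1], tree$phylo$edge[, 2])
  key_po <- paste(phylo$edge[, 1], phylo$edge[, 2])
  fg <- tree$foreground[match(key_po, key_orig)]
  ntip <- length(phylo$tip.label)
  E <- nrow(phylo$edge)
  root <- phylo$edge[E, 1]
  nnode <- E + 1L
  K <- length(mix$proportions)
  pi <- model$frequencies

  classes <- sample.int(K, n_codons, replace = TRUE, prob = mix$proportions)
  states <- matrix(0L, nnode, n_codons)
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)

  # transition matrices cached per (edge, omega value)
  Qcache <- new.env(parent = emptyenv())
  getQ <- function(omega) {
    key <- format(omega, digits = 15)
    if (is.null(Qcache[[key]]))
      Qcache[[key]] <- build_rate_matrix(model$kappa, omega, pi)
    Qcache[[key]]
  }
  # mixture-average branch-length scaling: class k on an edge evolves at
  # rate (a + omega_k b) / sum_k p_k (a + omega_k b), so a branch length is
  # the expected number of substitutions per codon averaged over classes
  fl <- codon_flow(model$kappa, pi)
  for (e in E:1) {  # reverse postorder = parents before children
    parent <- phylo$edge[e, 1]; child <- phylo$edge[e, 2]
    t <- phylo$edge.length[e]
    omegas_edge <- if (fg[e]) mix$omega_fg else mix$omega_bg
    rates <- fl["a"] + fl["b"] * omegas_edge
    mult <- rates / sum(mix$proportions * rates)
    for (k in unique(classes)) {
      sites <- which(classes == k)
      P <- transition_matrix(getQ(omegas_edge[k]), t * mult[k], pi)
      ps <- states[parent, sites]
      for (s0 in unique(ps)) {
        sel <- sites[ps == s0]
        states[child, sel] <- sample.int(61, length(sel), replace = TRUE,
                                         prob = P[s0, ])
      }
    }
  }
  cods <- codon_table()$codons
  seqs <- vapply(seq_len(ntip), function(i)
    paste0(cods[states[i, ]], collapse = ""), "")
  names(seqs) <- phylo$tip.label
  structure(list(
    alignment = codon_alignment(seqs),
    true_classes = mix$labels[classes],
    params = list(model = model, tree = tree, n_codons = n_codons),
    seed = seed
  ), class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("simulated codon alignment:", length(x$alignment$taxa), "taxa x",
      x$alignment$n_codons, "codons; classes:",
      paste(names(table(x$true_classes)), table(x$true_classes),
            sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated replicate to disk
#'
#' Writes the alignment (FASTA or PHYLIP) plus a sidecar TSV of true site
#' classes.
#'
#' @param rep A `sim_replicate`.
#' @param prefix Output path prefix; writes `<prefix>.fasta` (or `.phy`)
#'   and `<prefix>.classes.tsv`.
#' @param format Alignment format.
#' @export
write_replicate <- function(rep, prefix, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  ext <- if (format == "fasta") ".fasta" else ".phy"
  write_codon_alignment(rep$alignment, paste0(prefix, ext), format)
  utils::write.table(
    data.frame(site = seq_along(rep$true_classes),
               class = rep$true_classes),
    paste0(prefix, ".classes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}
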