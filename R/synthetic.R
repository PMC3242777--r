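# Synthetic-data generators emulating a divergent insect GST-type gene
# cluster: a GC3-biased codon usage table, random trees calibrated to a
# target synonymous divergence, and branch-site datasets with known true
# site classes. Everything here is generated in code; no network access.

# Frozen position-specific nucleotide frequencies behind the synthetic
# codon usage table (order T, C, A, G per position). Third positions are
# GC-rich, emulating the strong GC3 bias of the Anopheles gambiae genome.
CODON_USAGE_POS_FREQS <- matrix(
  c(0.19, 0.24, 0.26, 0.31,   # position 1
    0.28, 0.23, 0.30, 0.19,   # position 2
    0.22, 0.31, 0.17, 0.30),  # position 3
  nrow = 3, byrow = TRUE, dimnames = list(NULL, c("T", "C", "A", "G")))

#' Synthetic codon usage table emulating Anopheles gambiae
#'
#' A frozen, versioned 61-vector of sense-codon frequencies. This is a
#' SYNTHETIC stand-in built from fixed position-specific nucleotide
#' frequencies with the GC-rich third codon position characteristic of the
#' *Anopheles gambiae* genome; it is not derived from genome data and is
#' intended to parameterize simulations, not to describe the species.
#'
#' @return Named numeric 61-vector summing to 1 (order of
#'   [sense_codons()]), all entries positive.
#' @export
gambiae_like_codon_usage <- function() {
  cods <- codon_table()$codons
  splits <- strsplit(cods, "")
  f <- vapply(splits, function(s)
    CODON_USAGE_POS_FREQS[1, s[1]] * CODON_USAGE_POS_FREQS[2, s[2]] *
      CODON_USAGE_POS_FREQS[3, s[3]], 0)
  stats::setNames(f / sum(f), cods)
}

#' Template for GSTall-like synthetic datasets
#'
#' Default values emulate the study dataset this package's simulation
#' harness targets: 31 taxa, 257 codons, four branch-site classes with
#' most sites under strong purifying selection, and pairwise synonymous
#' divergence calibrated to mean 1.6 (s.d. 0.7) as in divergent paralog
#' comparisons. The class proportions (p0 = 0.80, p1 = 0.15, 5% positively
#' selected) are explicit assumptions, overridable per argument.
#'
#' @param n_taxa,n_codons Alignment dimensions.
#' @param codon_usage 61-vector of codon frequencies.
#' @param p0,p1 Background class proportions (purifying / neutral).
#' @param omega0 Purifying-class omega.
#' @param omega2 Foreground omega for A2-generated data.
#' @param kappa Transition/transversion ratio.
#' @param target_ks Named vector `c(mean = , sd = )` calibration target for
#'   pairwise synonymous divergence.
#' @return List of class `dataset_template`.
#' @export
dataset_template <- function(n_taxa = 31, n_codons = 257,
                             codon_usage = gambiae_like_codon_usage(),
                             p0 = 0.80, p1 = 0.15,
                             omega0 = 0.09, omega2 = 9, kappa = 2,
                             target_ks = c(mean = 1.6, sd = 0.7)) {
  if (abs(sum(codon_usage) - 1) > 1e-6) stop("codon usage must sum to 1")
  if (p0 + p1 > 1 || p0 < 0 || p1 < 0) stop("invalid class proportions")
  if (target_ks["mean"] <= 0) stop("target kS mean must be > 0")
  structure(list(n_taxa = n_taxa, n_codons = n_codons,
                 codon_usage = codon_usage, p0 = p0, p1 = p1,
                 omega0 = omega0, omega2 = omega2, kappa = kappa,
                 target_ks = target_ks),
            class = "dataset_template")
}

# Foreground branch length reproducing a target nonsynonymous divergence
# (dN, substitutions per nonsynonymous site) when the branch evolves under
# the template's branch-site foreground mixture with omega2 as in the
# moderate-selection condition. The emulated lineage's reported dN of 0.11
# anchors the default.
fg_anchor_length <- function(template, target_dn = 0.11) {
  fl <- codon_flow(template$kappa, template$codon_usage)
  p2 <- 1 - template$p0 - template$p1
  p <- c(template$p0, template$p1,
         p2 * template$p0 / (template$p0 + template$p1),
         p2 * template$p1 / (template$p0 + template$p1))
  w_fg <- c(template$omega0, 1, template$omega2, template$omega2)
  rbar <- fl["a"] + fl["b"] * sum(p * w_fg)
  rho_n <- fl["b"] / (fl["a"] + fl["b"])
  unname(target_dn * 3 * rho_n * rbar / (fl["b"] * sum(p * w_fg)))
}

# random rooted binary newick over the given leaf strings, with branch
# lengths drawn by len()
random_clade_newick <- function(leaves, len) {
  while (length(leaves) > 1) {
    i <- sample.int(length(leaves), 2)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", leaves[i[1]], len(),
                      leaves[i[2]], len())
    leaves <- c(leaves[-i], merged)
  }
  leaves
}

# classify edges as within-clade ("within") or paralog-level ("between",
# including each clade's subtending branch) from the gX_ label prefixes
classify_gst_edges <- function(tree) {
  phylo <- tree$phylo
  ntip <- length(phylo$tip.label)
  clade_of <- sub("_.*$", "", phylo$tip.label)
  below <- vector("list", ntip + phylo$Nnode)
  po <- ape::reorder.phylo(phylo, "postorder")
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  vapply(seq_len(nrow(phylo$edge)), function(e) {
    tips <- below[[phylo$edge[e, 2]]]
    cl <- unique(clade_of[tips])
    if (length(cl) == 1 && length(tips) < sum(clade_of == cl[1]))
      "within" else "between"
  }, "")
}

#' Random gene-family tree calibrated to the two-level kS structure
#'
#' Emulates the phylogeny of a tandemly duplicated gene cluster sequenced
#' across species: taxa are grouped into paralog clades (genes), each clade
#' containing orthologs of one gene. A random topology is drawn for the
#' paralog backbone and within each clade; branch lengths are then
#' calibrated by simulation so that pairwise synonymous divergence (NG86
#' kS with Jukes-Cantor correction) matches the two printed summary levels:
#' between-clade (paralog) pairs near `target_ks` (mean 1.6) and
#' within-clade (ortholog) pairs near 1.1. The branch subtending one clade
#' is flagged foreground and its length set so that, under the template's
#' branch-site foreground mixture, the branch shows a nonsynonymous
#' divergence of about `fg_dn` — emulating the reported post-duplication
#' lineage (dN 0.11, among the longest nonsynonymous branches of the
#' original tree).
#'
#' @param seed Integer seed (calibration is reproducible given the seed).
#' @param n_taxa Number of taxa (`>= 4`); distributed over
#'   `max(2, round(n_taxa / 4.5))` paralog clades.
#' @param template A [dataset_template()] supplying the codon usage, kappa,
#'   purifying omega and kS target.
#' @param tol Calibration tolerance on the mean kS levels (default 0.25).
#' @param max_iter Calibration iteration cap.
#' @param calib_codons Codon count used for calibration simulations.
#' @param fg_dn Target foreground-branch nonsynonymous divergence
#'   (default 0.11).
#' @param target_ks_within Ortholog-level kS calibration target
#'   (default 1.1).
#' @return A [codon_tree()] with one foreground-flagged internal branch and
#'   attributes `ks_mean`, `ks_sd` (paralog level) and `ks_within`
#'   (ortholog level) recording the achieved calibration.
#' @export
gstall_like_tree <- function(seed, n_taxa = 31,
                             template = dataset_template(n_taxa = n_taxa),
                             tol = 0.25, max_iter = 15,
                             calib_codons = min(template$n_codons, 200),
                             fg_dn = 0.11, target_ks_within = 1.1) {
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  n_clades <- max(2, round(n_taxa / 4.5))
  sizes <- rep(n_taxa %/% n_clades, n_clades)
  extra <- n_taxa - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  len_within <- function() stats::rexp(1, 1 / 0.25) + 0.02
  len_between <- function() stats::rexp(1, 1 / 0.35) + 0.05
  clades <- vapply(seq_len(n_clades), function(g)
    random_clade_newick(sprintf("g%d_s%d", g, seq_len(sizes[g])),
                        len_within), "")
  newick <- paste0(random_clade_newick(clades, len_between), ";")
  tree <- read_tree(newick)
  # clade 1 (the duplication-descendant lineage) is the foreground: flag
  # the branch splitting clade 1's tips from the rest (located by tip set,
  # robust to how the unrooted representation is rooted)
  phylo <- tree$phylo
  ntip <- length(phylo$tip.label)
  clade1 <- which(grepl("^g1_", phylo$tip.label))
  po <- ape::reorder.phylo(phylo, "postorder")
  below <- vector("list", ntip + phylo$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1]]] <- c(below[[po$edge[e, 1]]],
                                below[[po$edge[e, 2]]])
  fg_edge <- which(vapply(seq_len(nrow(phylo$edge)), function(e) {
    tips <- sort(below[[phylo$edge[e, 2]]])
    identical(tips, sort(clade1)) ||
      identical(tips, sort(setdiff(seq_len(ntip), clade1)))
  }, FALSE))[1]
  if (is.na(fg_edge)) stop("internal error: clade-1 subtending edge not found")
  tree <- set_foreground(tree, fg_edge)

  edge_class <- classify_gst_edges(tree)
  model <- codon_model_spec(template$kappa, template$codon_usage,
                            model_mixture("M0",
                                          list(omega = template$omega0)))
  target_b <- unname(template$target_ks["mean"])
  target_w <- target_ks_within
  calib_seed <- as.integer((seed + 104729) %% .Machine$integer.max)
  ach_b <- NA_real_; ach_w <- NA_real_; ach_sd <- NA_real_
  for (it in seq_len(max_iter)) {
    rep <- simulate_alignment(tree, model, calib_codons,
                              seed = calib_seed + it)
    kt <- pairwise_divergence_table(rep$alignment)
    same <- sub("_.*$", "", kt$taxon_a) == sub("_.*$", "", kt$taxon_b)
    ks_w <- kt$ks[same & !is.na(kt$ks)]
    ks_b <- kt$ks[!same & !is.na(kt$ks)]
    if (!length(ks_b) || !length(ks_w)) {
      tree$phylo$edge.length <- tree$phylo$edge.length * 0.4
      next
    }
    ach_b <- mean(ks_b); ach_w <- mean(ks_w); ach_sd <- stats::sd(ks_b)
    if (abs(ach_b - target_b) <= tol && abs(ach_w - target_w) <= tol) break
    damp <- function(r) min(max(r^0.7, 0.4), 2.5)
    rw <- damp(target_w / ach_w)
    rb <- damp(target_b / ach_b)
    wsel <- edge_class == "within"
    tree$phylo$edge.length[wsel] <-
      pmin(tree$phylo$edge.length[wsel] * rw, 40)
    tree$phylo$edge.length[!wsel] <-
      pmin(tree$phylo$edge.length[!wsel] * rb, 40)
  }
  if (is.na(ach_b) || abs(ach_b - target_b) > 2 * tol)
    stop("kS calibration failed: paralog-level mean ", signif(ach_b, 3),
         " vs target ", target_b, " after ", max_iter, " iterations")
  # pin the foreground branch to the dN-anchored length
  tree$phylo$edge.length[which(tree$foreground)] <-
    fg_anchor_length(template, fg_dn)
  attr(tree, "ks_mean") <- ach_b
  attr(tree, "ks_sd") <- ach_sd
  attr(tree, "ks_within") <- ach_w
  tree
}

#' Branch-site model specification from a template
#'
#' @param template A [dataset_template()].
#' @param generating_model `"A1"` (null) or `"A2"` (positive selection with
#'   the template's `omega2`).
#' @return A [codon_model_spec()].
#' @export
template_model <- function(template, generating_model = c("A1", "A2")) {
  generating_model <- match.arg(generating_model)
  params <- list(p0 = template$p0, p1 = template$p1,
                 omega0 = template$omega0, omega2 = template$omega2)
  codon_model_spec(template$kappa, template$codon_usage,
                   model_mixture(generating_model, params))
}

#' Generate one GSTall-like dataset
#'
#' Simulates a codon alignment on `tree` under branch-site model A1 or A2
#' with the template's class proportions, recording true per-site classes.
#'
#' @param template A [dataset_template()].
#' @param generating_model `"A1"` or `"A2"`.
#' @param seed Integer seed (same seed, identical dataset).
#' @param tree Optional [codon_tree()]; by default a calibrated
#'   [gstall_like_tree()] is drawn from the same seed.
#' @return A `sim_replicate` (see [simulate_alignment()]).
#' @export
make_dataset <- function(template = dataset_template(),
                         generating_model = c("A1", "A2"), seed = 1,
                         tree = NULL) {
  generating_model <- match.arg(generating_model)
  if (is.null(tree))
    tree <- gstall_like_tree(seed, n_taxa = template$n_taxa,
                             template = template)
  model <- template_model(template, generating_model)
  simulate_alignment(tree, model, template$n_codons, seed = seed)
}
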