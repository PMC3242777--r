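# Codon substitution model specifications: equilibrium frequencies, the
# site-class mixture structure housing every model in the catalogue, and
# the Muse-Gaut/Goldman-Yang style rate matrix.

MODEL_CATALOGUE <- c("M0", "M1a", "M2a", "M7", "M8", "M8a",
                     "branch0", "branch1", "branch2_strict",
                     "branch2_relaxed", "A1", "A2")

# omega-type free parameter counts (excluding kappa and branch lengths);
# branch1 depends on the branch count and is handled in n_free_params()
OMEGA_PARAM_COUNT <- c(M0 = 1, M1a = 2, M2a = 4, M7 = 2, M8 = 4, M8a = 3,
                       branch0 = 1, branch2_strict = 2, branch2_relaxed = 1,
                       A1 = 3, A2 = 4)

#' Site-class mixture
#'
#' The omega-heterogeneity structure shared by every model: a set of site
#' classes, each with a proportion and a background and foreground omega.
#' For models without branch heterogeneity the two omegas coincide.
#'
#' @param proportions Numeric vector summing to 1.
#' @param omega_bg,omega_fg Numeric vectors of background / foreground
#'   dN/dS per class (all `>= 0`).
#' @param model_name Optional catalogue name.
#' @param labels Optional class labels (e.g. `c("0","1","2a","2b")`).
#' @return Object of class `site_class_mixture`.
#' @export
site_class_mixture <- function(proportions, omega_bg, omega_fg = omega_bg,
                               model_name = NULL, labels = NULL) {
  if (abs(sum(proportions) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (any(proportions < -1e-12)) stop("class proportions must be >= 0")
  if (any(omega_bg < 0) || any(omega_fg < 0)) stop("omega must be >= 0")
  k <- length(proportions)
  if (length(omega_bg) != k || length(omega_fg) != k)
    stop("omega vectors must match the number of classes")
  if (is.null(labels)) labels <- as.character(seq_len(k) - 1L)
  structure(list(proportions = pmax(proportions, 0) / sum(pmax(proportions, 0)),
                 omega_bg = omega_bg, omega_fg = omega_fg,
                 model_name = model_name, labels = labels),
            class = "site_class_mixture")
}

#' Discretize a beta distribution into equal-probability categories
#'
#' Categories are represented by their within-category means, the standard
#' discretization for the beta site-class models (M7/M8/M8a).
#'
#' @param p,q Beta shape parameters (`> 0`).
#' @param n Number of categories (default 10).
#' @return Numeric vector of `n` category mean omegas in `(0, 1)`.
#' @export
beta_category_means <- function(p, q, n = 10) {
  if (p <= 0 || q <= 0) stop("beta shapes must be positive")
  bounds <- stats::qbeta(seq(0, 1, length.out = n + 1), p, q)
  means <- n * (p / (p + q)) *
    (stats::pbeta(bounds[-1], p + 1, q) - stats::pbeta(bounds[-(n + 1)], p + 1, q))
  # guard against numerical loss at extreme shapes
  pmin(pmax(means, 1e-9), 1 - 1e-9)
}

#' Build the site-class mixture for a catalogue model
#'
#' @param model_name One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`,
#'   `"M8a"`, `"branch0"`, `"branch1"`, `"branch2_strict"`,
#'   `"branch2_relaxed"`, `"A1"`, `"A2"`.
#' @param params Named list of the model's mixture parameters:
#'   \describe{
#'     \item{M0/branch0}{`omega`}
#'     \item{M1a}{`p0`, `omega0`}
#'     \item{M2a}{`p0`, `p1`, `omega0`, `omega2`}
#'     \item{M7}{`p`, `q`}
#'     \item{M8}{`p0`, `p`, `q`, `omega_s`}
#'     \item{M8a}{`p0`, `p`, `q` (`omega_s` fixed at 1)}
#'     \item{branch1}{`omega` vector, one per branch (handled in fitting)}
#'     \item{branch2_strict}{`omega_bg`, `omega_fg`}
#'     \item{branch2_relaxed}{`omega_bg` (`omega_fg` fixed at 1)}
#'     \item{A1}{`p0`, `p1`, `omega0` (foreground omega2 fixed at 1)}
#'     \item{A2}{`p0`, `p1`, `omega0`, `omega2`}
#'   }
#' @param n_beta Categories for beta discretization (default 10).
#' @return A [site_class_mixture()] (for `branch1` a one-class mixture;
#'   per-branch omegas live in the fit machinery).
#' @export
model_mixture <- function(model_name, params, n_beta = 10) {
  model_name <- match.arg(model_name, MODEL_CATALOGUE)
  P <- params
  mix <- switch(model_name,
    M0 = ,
    branch0 = site_class_mixture(1, P$omega, model_name = model_name),
    M1a = site_class_mixture(c(P$p0, 1 - P$p0), c(P$omega0, 1),
                             model_name = model_name),
    M2a = {
      p2 <- 1 - P$p0 - P$p1
      if (p2 < -1e-9) stop("p0 + p1 must be <= 1")
      site_class_mixture(c(P$p0, P$p1, max(p2, 0)), c(P$omega0, 1, P$omega2),
                         model_name = model_name)
    },
    M7 = {
      w <- beta_category_means(P$p, P$q, n_beta)
      site_class_mixture(rep(1 / n_beta, n_beta), w, model_name = model_name)
    },
    M8 = ,
    M8a = {
      omega_s <- if (model_name == "M8a") 1 else P$omega_s
      w <- beta_category_means(P$p, P$q, n_beta)
      site_class_mixture(c(rep(P$p0 / n_beta, n_beta), 1 - P$p0),
                         c(w, omega_s), model_name = model_name)
    },
    branch2_strict = site_class_mixture(1, P$omega_bg, P$omega_fg,
                                        model_name = model_name),
    branch2_relaxed = site_class_mixture(1, P$omega_bg, 1,
                                         model_name = model_name),
    branch1 = site_class_mixture(1, 1, model_name = model_name),
    A1 = ,
    A2 = {
      omega2 <- if (model_name == "A1") 1 else P$omega2
      p0 <- P$p0; p1 <- P$p1
      p2 <- 1 - p0 - p1
      if (p2 < -1e-9) stop("p0 + p1 must be <= 1")
      p2 <- max(p2, 0)
      # classes 2a/2b split the positively selected proportion in the ratio
      # p0:p1, mirroring the background composition
      denom <- p0 + p1
      if (denom <= 0) stop("p0 + p1 must be > 0")
      site_class_mixture(c(p0, p1, p2 * p0 / denom, p2 * p1 / denom),
                         c(P$omega0, 1, P$omega0, 1),
                         c(P$omega0, 1, omega2, omega2),
                         model_name = model_name,
                         labels = c("0", "1", "2a", "2b"))
    })
  mix
}

#' Codon model specification
#'
#' @param kappa Transition/transversion rate ratio (`> 0`).
#' @param frequencies 61-vector of sense-codon equilibrium frequencies
#'   summing to 1 (order of [sense_codons()]).
#' @param mixture A [site_class_mixture()].
#' @param frequency_mode Provenance tag: `"equal"`, `"F1x4"`, `"F3x4"` or
#'   `"F61"`.
#' @return Object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(kappa, frequencies, mixture,
                             frequency_mode = "F61") {
  if (kappa <= 0) stop("kappa must be > 0")
  if (length(frequencies) != 61) stop("frequencies must have length 61")
  if (any(frequencies < 0)) stop("frequencies must be >= 0")
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  structure(list(kappa = kappa,
                 frequencies = frequencies / sum(frequencies),
                 mixture = mixture, frequency_mode = frequency_mode),
            class = "codon_model_spec")
}

#' Codon equilibrium frequencies from an alignment
#'
#' `F3x4` builds codon frequencies from the observed nucleotide frequencies
#' at each codon position (the default of the standard ML codon software),
#' `F1x4` from overall nucleotide frequencies, `F61` from observed codon
#' counts (with a small pseudo-count), `equal` gives 1/61.
#'
#' @param aln A [codon_alignment()].
#' @param mode One of `"F3x4"`, `"F1x4"`, `"F61"`, `"equal"`.
#' @return Named 61-vector summing to 1.
#' @export
codon_frequencies <- function(aln, mode = c("F3x4", "F1x4", "F61", "equal")) {
  mode <- match.arg(mode)
  cods <- codon_table()$codons
  if (mode == "equal")
    return(stats::setNames(rep(1 / 61, 61), cods))
  counts <- tabulate(aln$codes[!is.na(aln$codes)], nbins = 61)
  if (mode == "F61") {
    f <- counts + 0.5
    return(stats::setNames(f / sum(f), cods))
  }
  splits <- strsplit(cods, "")
  posmat <- matrix(unlist(splits), ncol = 3, byrow = TRUE)
  if (mode == "F1x4") {
    ntf <- stats::setNames(numeric(4), NUC)
    for (p in 1:3) for (nt in NUC)
      ntf[nt] <- ntf[nt] + sum(counts[posmat[, p] == nt])
    ntf <- (ntf + 1) / sum(ntf + 1)
    f <- ntf[posmat[, 1]] * ntf[posmat[, 2]] * ntf[posmat[, 3]]
  } else {
    posfreq <- matrix(0, 4, 3, dimnames = list(NUC, NULL))
    for (p in 1:3) for (nt in NUC)
      posfreq[nt, p] <- sum(counts[posmat[, p] == nt])
    posfreq <- sweep(posfreq + 1, 2, colSums(posfreq + 1), "/")
    ridx <- match(posmat, NUC)
    dim(ridx) <- dim(posmat)
    f <- posfreq[cbind(ridx[, 1], 1)] * posfreq[cbind(ridx[, 2], 2)] *
      posfreq[cbind(ridx[, 3], 3)]
  }
  stats::setNames(f / sum(f), cods)
}

#' Codon substitution rate matrix
#'
#' Builds the 61x61 generator with entries proportional to
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]` for codon pairs one
#' nucleotide apart (zero otherwise), scaled so the expected number of
#' substitutions per codon per unit time is 1 at stationarity.
#'
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS ratio.
#' @param frequencies 61-vector of codon frequencies summing to 1.
#' @return 61x61 generator matrix (rows sum to 0).
#' @export
build_rate_matrix <- function(kappa, omega, frequencies) {
  if (length(frequencies) != 61 || abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must be a 61-vector summing to 1")
  if (kappa <= 0 || omega < 0) stop("kappa must be > 0 and omega >= 0")
  type <- codon_pair_type()
  fac <- c(kappa, 1, kappa * omega, omega)  # syn ts, syn tv, nonsyn ts, nonsyn tv
  S <- matrix(0, 61, 61)
  nz <- type > 0
  S[nz] <- fac[type[nz]]
  Q <- S * rep(frequencies, each = 61)  # Q_ij = S_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(frequencies * diag(Q))
  Q / scale
}

#' Transition probability matrix
#'
#' `P(t) = exp(Qt)` computed through the symmetric eigendecomposition that
#' reversibility affords.
#'
#' @param Q Generator from [build_rate_matrix()].
#' @param t Branch length (expected substitutions per codon, `>= 0`).
#' @param frequencies The stationary frequencies used to build `Q`.
#' @return 61x61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t, frequencies) {
  if (t < 0) stop("branch length must be >= 0")
  sq <- sqrt(frequencies)
  B <- Q * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  A <- e$vectors / sq
  Ainv <- t(e$vectors) * rep(sq, each = 61)
  P <- (A * rep(exp(e$values * t), each = 61)) %*% Ainv
  P[P < 0] <- 0
  P / rowSums(P)
}
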