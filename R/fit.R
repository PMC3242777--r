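# Maximum-likelihood fitting of the model catalogue. Branch lengths, kappa
# and the model's mixture parameters are optimized jointly by bounded
# quasi-Newton (L-BFGS-B) on transformed coordinates (log for rates and
# branch lengths, logit/stick-breaking for proportions), with analytic
# branch-length gradients from the pruning core and finite differences for
# the few scalar model parameters. Multiple restarts from perturbed
# starting points guard against local optima.

OMEGA_MAX <- 999
OMEGA_MIN <- 1e-6
KAPPA_BOUNDS <- c(1e-3, 100)
BLEN_BOUNDS <- c(1e-6, 50)

# scalar parameter descriptions per model: name, transform, init, natural
# bounds. Builders turn the named natural values into model_mixture params.
scalar_spec <- function(model_name, n_edges) {
  p <- function(name, trans, init, lo, hi)
    list(name = name, trans = trans, init = init, lo = lo, hi = hi)
  om_free <- function(name, init) p(name, "log", init, OMEGA_MIN, OMEGA_MAX)
  om_unit <- function(name, init) p(name, "logit", init, 1e-6, 1 - 1e-9)
  om_pos <- function(name, init) p(name, "log", init, 1, OMEGA_MAX)
  prop <- function(name, init) p(name, "logit", init, 1e-6, 1 - 1e-6)
  shape <- function(name, init) p(name, "log", init, 0.005, 99)
  switch(model_name,
    M0 = ,
    branch0 = list(om_free("omega", 0.4)),
    M1a = list(prop("p0", 0.7), om_unit("omega0", 0.2)),
    M2a = list(prop("sp0", 0.7), prop("sp1", 0.8),
               om_unit("omega0", 0.2), om_pos("omega2", 3)),
    M7 = list(shape("p", 0.5), shape("q", 1.5)),
    M8 = list(prop("p0", 0.9), shape("p", 0.5), shape("q", 1.5),
              om_pos("omega_s", 2)),
    M8a = list(prop("p0", 0.9), shape("p", 0.5), shape("q", 1.5)),
    branch2_strict = list(om_unit("omega_bg", 0.2), om_free("omega_fg", 1.5)),
    branch2_relaxed = list(om_unit("omega_bg", 0.2)),
    A1 = list(prop("sp0", 0.75), prop("sp1", 0.8), om_unit("omega0", 0.1)),
    A2 = list(prop("sp0", 0.75), prop("sp1", 0.8), om_unit("omega0", 0.1),
              om_pos("omega2", 3)),
    branch1 = lapply(seq_len(n_edges), function(e)
      om_free(paste0("omega_b", e), 0.4)),
    stop("unknown model: ", model_name))
}

# stick-breaking (sp0, sp1) -> (p0, p1)
stick_to_props <- function(sp0, sp1) {
  p0 <- sp0
  p1 <- (1 - p0) * sp1
  list(p0 = p0, p1 = p1)
}
props_to_stick <- function(p0, p1) {
  list(sp0 = p0, sp1 = if (p0 < 1) p1 / (1 - p0) else 0.5)
}

mixture_params_from_scalars <- function(model_name, sc) {
  switch(model_name,
    M0 = ,
    branch0 = list(omega = sc$omega),
    M1a = list(p0 = sc$p0, omega0 = sc$omega0),
    M2a = {
      pr <- stick_to_props(sc$sp0, sc$sp1)
      list(p0 = pr$p0, p1 = pr$p1, omega0 = sc$omega0, omega2 = sc$omega2)
    },
    M7 = list(p = sc$p, q = sc$q),
    M8 = list(p0 = sc$p0, p = sc$p, q = sc$q, omega_s = sc$omega_s),
    M8a = list(p0 = sc$p0, p = sc$p, q = sc$q),
    branch2_strict = list(omega_bg = sc$omega_bg, omega_fg = sc$omega_fg),
    branch2_relaxed = list(omega_bg = sc$omega_bg),
    A1 = {
      pr <- stick_to_props(sc$sp0, sc$sp1)
      list(p0 = pr$p0, p1 = pr$p1, omega0 = sc$omega0)
    },
    A2 = {
      pr <- stick_to_props(sc$sp0, sc$sp1)
      list(p0 = pr$p0, p1 = pr$p1, omega0 = sc$omega0, omega2 = sc$omega2)
    },
    branch1 = NULL)
}

trans_fwd <- function(v, trans) switch(trans, log = log(v),
                                       logit = stats::qlogis(v), v)
trans_inv <- function(x, trans) switch(trans, log = exp(x),
                                       logit = stats::plogis(x), x)

#' Number of free omega-type parameters of a catalogue model
#'
#' Counts the independently optimized mixture/omega parameters, excluding
#' kappa and branch lengths which are common to all models. For the
#' free-ratio branch model the count equals the number of branches.
#'
#' @param model_name Catalogue model name.
#' @param tree A `codon_tree` (needed for `branch1`).
#' @return Integer count.
#' @export
n_free_params <- function(model_name, tree = NULL) {
  if (model_name == "branch1") {
    if (is.null(tree)) stop("branch1 parameter count needs the tree")
    return(n_branches(tree))
  }
  unname(OMEGA_PARAM_COUNT[model_name])
}

#' Fit a codon model by maximum likelihood
#'
#' Maximizes the log-likelihood over branch lengths, kappa and the model's
#' free mixture parameters within bounds, running `restarts` optimizations
#' from distinct starting points and returning the best.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [codon_tree()]; its branch lengths serve as starting
#'   values. Branch-site models (`A1`, `A2`) and branch models require a
#'   foreground flag.
#' @param model_name Catalogue model name (see [model_mixture()]).
#' @param frequencies Codon equilibrium frequencies; default `F3x4`
#'   estimated from the alignment.
#' @param restarts Number of optimization restarts (default 3).
#' @param fix_branch_lengths If `TRUE`, branch lengths are held at the tree
#'   values and only kappa and mixture parameters are optimized.
#' @param fix_kappa Optional fixed kappa (numeric) instead of optimizing it.
#' @param init Named list of natural-scale starting values overriding the
#'   defaults (`kappa`, `omega0`, `p0`, `p1`, `omega2`, ...).
#' @param maxit,factr L-BFGS-B control parameters.
#' @return Object of class `codon_fit`: `lnL`, `kappa`, `params` (natural
#'   mixture parameters), `mixture`, `tree` (fitted branch lengths),
#'   `n_free_params`, `convergence` (per-restart status and lnL),
#'   `frequencies`, `model`.
#' @export
fit_model <- function(aln, tree, model_name,
                      frequencies = NULL,
                      restarts = 3,
                      fix_branch_lengths = FALSE,
                      fix_kappa = NULL,
                      init = list(),
                      maxit = 200, factr = 1e9) {
  model_name <- match.arg(model_name, MODEL_CATALOGUE)
  ctx <- lik_context(aln, tree)
  if (is.null(frequencies)) frequencies <- codon_frequencies(aln, "F3x4")
  needs_fg <- model_name %in% c("branch1", "branch2_strict",
                                "branch2_relaxed", "A1", "A2")
  if (needs_fg && model_name %in% c("branch2_strict", "branch2_relaxed",
                                    "A1", "A2") && !any(ctx$foreground))
    stop("model '", model_name, "' requires a foreground branch flag ('#1')")

  spec <- scalar_spec(model_name, ctx$n_edges)
  est_kappa <- is.null(fix_kappa)
  if (est_kappa)
    spec <- c(list(list(name = "kappa", trans = "log",
                        init = if (!is.null(init$kappa)) init$kappa else 2,
                        lo = KAPPA_BOUNDS[1], hi = KAPPA_BOUNDS[2])), spec)
  # apply user inits (p0/p1 arrive on the natural scale)
  if (!is.null(init$p0)) {
    st <- props_to_stick(init$p0, if (!is.null(init$p1)) init$p1
                         else (1 - init$p0) * 0.8)
    init$sp0 <- st$sp0; init$sp1 <- st$sp1
  }
  for (i in seq_along(spec)) {
    nm <- spec[[i]]$name
    if (!is.null(init[[nm]]))
      spec[[i]]$init <- min(max(init[[nm]], spec[[i]]$lo), spec[[i]]$hi)
  }
  ns <- length(spec)
  sc_lo <- vapply(spec, function(s) trans_fwd(s$lo, s$trans), 0)
  sc_hi <- vapply(spec, function(s) trans_fwd(s$hi, s$trans), 0)
  sc_init <- vapply(spec, function(s)
    min(max(trans_fwd(s$init, s$trans), trans_fwd(s$lo, s$trans)),
        trans_fwd(s$hi, s$trans)), 0)
  bl_init <- log(pmin(pmax(ctx$edge_length, BLEN_BOUNDS[1]), BLEN_BOUNDS[2]))
  nb <- if (fix_branch_lengths) 0L else ctx$n_edges
  lower <- c(sc_lo, rep(log(BLEN_BOUNDS[1]), nb))
  upper <- c(sc_hi, rep(log(BLEN_BOUNDS[2]), nb))

  is_branch1 <- model_name == "branch1"
  unpack <- function(x) {
    sc <- stats::setNames(
      lapply(seq_len(ns), function(i) trans_inv(x[i], spec[[i]]$trans)),
      vapply(spec, `[[`, "", "name"))
    blen <- if (fix_branch_lengths) ctx$edge_length else exp(x[ns + seq_len(nb)])
    kappa <- if (est_kappa) sc$kappa else fix_kappa
    if (is_branch1) {
      pbo <- unlist(sc[grepl("^omega_b", names(sc))], use.names = FALSE)
      list(kappa = kappa, blen = blen, mixture = model_mixture("branch0",
           list(omega = 1)), per_branch = pbo, sc = sc)
    } else {
      mp <- mixture_params_from_scalars(model_name, sc)
      list(kappa = kappa, blen = blen,
           mixture = model_mixture(model_name, mp), per_branch = NULL,
           sc = sc, mix_params = mp)
    }
  }

  last <- new.env(parent = emptyenv())
  eval_lnL <- function(x, gradient = FALSE) {
    u <- unpack(x)
    ctx_loglik(ctx, u$kappa, frequencies, u$mixture, edge_length = u$blen,
               per_branch_omega = u$per_branch, gradient = gradient)
  }
  fn <- function(x) {
    res <- eval_lnL(x)
    last$x <- x; last$lnL <- res$lnL
    if (!is.finite(res$lnL)) return(1e10)
    -res$lnL
  }
  # scalars that act on the likelihood only through the class proportions
  # get analytic derivatives via d lnL / d w_k; the rest (rates, shapes)
  # use forward differences
  weight_only <- vapply(spec, function(s)
    s$name %in% c("sp0", "sp1") ||
      (s$name == "p0" && model_name %in% c("M1a", "M8", "M8a")), FALSE)
  if (is_branch1) weight_only[] <- FALSE
  gr <- function(x) {
    res <- eval_lnL(x, gradient = nb > 0)
    g <- numeric(length(x))
    if (nb > 0) {
      t_nat <- exp(x[ns + seq_len(nb)])
      g[ns + seq_len(nb)] <- res$grad * t_nat
    }
    h <- 1e-5
    f0 <- res$lnL
    if (any(weight_only)) {
      # d lnL / d w_k with per-pattern weights
      csl <- res$classSiteLoglik
      sl <- res$siteLoglik
      dldw <- as.vector(exp(sweep(csl, 2, sl)) %*% ctx$pattern_weights)
      w0 <- unpack(x)$mixture$proportions
    }
    for (i in seq_len(ns)) {
      xi <- x
      xi[i] <- xi[i] + h
      if (weight_only[i]) {
        wi <- unpack(xi)$mixture$proportions
        g[i] <- sum((wi - w0) / h * dldw)
      } else {
        g[i] <- (eval_lnL(xi)$lnL - f0) / h
      }
    }
    -g
  }
  use_gr <- !is_branch1

  # deterministic restart perturbations (no RNG side effects)
  perturb <- function(x0, r) {
    if (r == 1) return(x0)
    off <- 0.5 * (r - 1) * rep_len(c(1, -1), ns) * rep_len(c(1, 1, -1), ns)
    x <- x0
    x[seq_len(ns)] <- pmin(pmax(x0[seq_len(ns)] + off, lower[seq_len(ns)]),
                           upper[seq_len(ns)])
    if (nb > 0) {
      bl_off <- 0.15 * (r - 1) * rep_len(c(1, -1), nb)
      x[ns + seq_len(nb)] <- pmin(pmax(x[ns + seq_len(nb)] + bl_off,
                                       log(BLEN_BOUNDS[1])),
                                  log(BLEN_BOUNDS[2]))
    }
    x
  }

  x0 <- c(sc_init, if (nb > 0) bl_init)
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    xr <- perturb(x0, r)
    opt <- try(stats::optim(xr, fn, gr = if (use_gr) gr else NULL,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = maxit, factr = factr)),
               silent = TRUE)
    if (inherits(opt, "try-error")) {
      runs[[r]] <- list(lnL = -Inf, par = xr, convergence = 99L,
                        message = as.character(opt))
    } else {
      runs[[r]] <- list(lnL = -opt$value, par = opt$par,
                        convergence = opt$convergence,
                        message = opt$message)
    }
  }
  lnLs <- vapply(runs, `[[`, 0, "lnL")
  best <- which.max(lnLs)
  if (!is.finite(lnLs[best]))
    stop("all optimization restarts failed for model ", model_name)
  u <- unpack(runs[[best]]$par)

  fitted_tree <- tree
  if (!fix_branch_lengths) {
    # map postorder lengths back onto the input tree's edge order
    key_orig <- paste(tree$phylo$edge[, 1], tree$phylo$edge[, 2])
    key_po <- paste(ctx$edge[, 1], ctx$edge[, 2])
    fitted_tree$phylo$edge.length[match(key_po, key_orig)] <- u$blen
  }
  params <- if (is_branch1) list(omega = u$per_branch) else u$mix_params
  conv <- data.frame(restart = seq_len(restarts), lnL = lnLs,
                     code = vapply(runs, `[[`, 0L, "convergence"))
  structure(list(
    model = model_name, lnL = lnLs[best], kappa = u$kappa,
    params = params, mixture = if (is_branch1) NULL else u$mixture,
    per_branch_omega = u$per_branch,
    tree = fitted_tree, frequencies = frequencies,
    n_free_params = n_free_params(model_name, tree),
    convergence = conv,
    converged = runs[[best]]$convergence == 0L,
    restart_spread = if (restarts > 1) diff(range(lnLs[is.finite(lnLs)]))
                     else 0
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit:", x$model, "\n")
  cat("  lnL =", format(x$lnL, digits = 10), "\n")
  cat("  kappa =", signif(x$kappa, 4), "\n")
  if (!is.null(x$params) && x$model != "branch1") {
    pv <- unlist(x$params)
    cat("  ", paste(names(pv), signif(pv, 4), sep = " = ",
                    collapse = ", "), "\n")
  }
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

# fraction of substitutions that are synonymous under Q(kappa, omega, pi)
syn_fraction <- function(kappa, omega, frequencies) {
  Q <- build_rate_matrix(kappa, omega, frequencies)
  type <- codon_pair_type()
  syn <- type == 1L | type == 2L
  sum(frequencies * rowSums(Q * syn))
}

#' Per-branch dN and dS from a branch-model fit
#'
#' Converts each branch's length and omega into synonymous and
#' nonsynonymous substitutions per site, using the neutral synonymous
#' substitution fraction to define site proportions. Supports foreground
#' branch selection workflows: branches are ranked by dN.
#'
#' @param fit A `codon_fit` from model `branch0`, `branch1`,
#'   `branch2_strict` or `branch2_relaxed`.
#' @return Data frame with one row per branch: `edge`, `length`, `omega`,
#'   `dN`, `dS`, `dN_rank` (1 = highest dN), `foreground`.
#' @export
branch_dn_ds <- function(fit) {
  tree <- fit$tree
  E <- n_branches(tree)
  omega <- switch(fit$model,
    branch0 = rep(fit$params$omega, E),
    branch1 = {
      # per-branch omegas follow the postorder used in fitting; map back
      po <- ape::reorder.phylo(tree$phylo, "postorder")
      key_orig <- paste(tree$phylo$edge[, 1], tree$phylo$edge[, 2])
      key_po <- paste(po$edge[, 1], po$edge[, 2])
      out <- numeric(E)
      out[match(key_po, key_orig)] <- fit$per_branch_omega
      out
    },
    branch2_strict = ifelse(tree$foreground, fit$params$omega_fg,
                            fit$params$omega_bg),
    branch2_relaxed = ifelse(tree$foreground, 1, fit$params$omega_bg),
    stop("branch_dn_ds needs a branch-model fit"))
  rhoS <- syn_fraction(fit$kappa, 1, fit$frequencies)
  t <- tree$phylo$edge.length
  fS <- vapply(omega, function(w) syn_fraction(fit$kappa, w,
                                               fit$frequencies), 0)
  dS <- t * fS / (3 * rhoS)
  dN <- t * (1 - fS) / (3 * (1 - rhoS))
  data.frame(edge = seq_len(E), length = t, omega = omega, dN = dN, dS = dS,
             dN_rank = rank(-dN, ties.method = "min"),
             foreground = tree$foreground)
}
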