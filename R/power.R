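# Simulation study of the branch-site test: replicate generation, A1/A2
# fitting, LRT decisions and BEB site-detection scoring against the true
# simulated site classes (power, accuracy, false-positive rate).

#' Configuration for a power / false-positive-rate study
#'
#' @param generating_model `"A1"` (null; the study measures the test's
#'   false-positive rate) or `"A2"` (the study measures power).
#' @param omega2 Foreground omega for A2-generated data (the study grid in
#'   the emulated study is 4, 9, 999).
#' @param n_replicates Number of simulated datasets (`>= 1`).
#' @param alpha LRT significance level (default 0.05).
#' @param beb_thresholds Posterior thresholds for site flagging.
#' @param branch_scale Factor applied to every branch length before
#'   simulation (0.5 and 2 probe the saturation sensitivity of the test).
#' @param template A [dataset_template()]; its `n_taxa`/`n_codons` set the
#'   study scale.
#' @param tree Optional pre-calibrated [codon_tree()]; generated from the
#'   study seed when `NULL`.
#' @param restarts Optimization restarts per fit (study profile default 1;
#'   the alternative fit is warm-started from the null solution, which
#'   enforces the nesting inequality).
#' @param reuse_null_lengths If `TRUE` (study profile default), the A2 fit
#'   holds branch lengths and kappa at the fitted A1 values; if `FALSE`,
#'   A2 re-optimizes everything jointly.
#' @param run_beb Run BEB site detection on LRT-significant replicates.
#' @return List of class `power_config`.
#' @export
power_config <- function(generating_model = c("A1", "A2"), omega2 = 9,
                         n_replicates = 100, alpha = 0.05,
                         beb_thresholds = c(0.95, 0.99), branch_scale = 1,
                         template = dataset_template(), tree = NULL,
                         restarts = 1, reuse_null_lengths = TRUE,
                         run_beb = TRUE) {
  generating_model <- match.arg(generating_model)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (branch_scale <= 0) stop("branch_scale must be > 0")
  template$omega2 <- omega2
  structure(list(generating_model = generating_model, omega2 = omega2,
                 n_replicates = n_replicates, alpha = alpha,
                 beb_thresholds = sort(beb_thresholds),
                 branch_scale = branch_scale, template = template,
                 tree = tree, restarts = restarts,
                 reuse_null_lengths = reuse_null_lengths,
                 run_beb = run_beb),
            class = "power_config")
}

#' Site-detection confusion metrics
#'
#' Scores BEB-flagged sites against the true simulated classes. True
#' positives are sites whose true class is 2a or 2b.
#'
#' @param flagged_sites Integer site indices flagged as positively
#'   selected.
#' @param true_classes Character vector of true per-site class labels
#'   (`"0"`, `"1"`, `"2a"`, `"2b"`).
#' @return List: `power` (detected true / all true), `accuracy` (detected
#'   true / all detected; `NA` when nothing is detected), `fpr` (detected
#'   non-true / all non-true), and the underlying confusion counts.
#' @export
site_detection_metrics <- function(flagged_sites, true_classes) {
  S <- length(true_classes)
  if (length(flagged_sites) && max(flagged_sites) > S)
    stop("flagged site index exceeds the number of sites")
  truth <- true_classes %in% c("2a", "2b")
  det <- rep(FALSE, S)
  det[flagged_sites] <- TRUE
  tp <- sum(det & truth); fp <- sum(det & !truth)
  n_true <- sum(truth); n_false <- S - n_true
  list(power = if (n_true > 0) tp / n_true else NA_real_,
       accuracy = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       fpr = if (n_false > 0) fp / n_false else NA_real_,
       tp = tp, fp = fp, n_true = n_true, n_false = n_false)
}

# fit the A1/A2 pair on one replicate; warm starts keep single-restart fits
# robust and guarantee lnL(A2) >= lnL(A1)
fit_branch_site_pair <- function(aln, tree, config, freqs = NULL) {
  if (is.null(freqs)) freqs <- codon_frequencies(aln, "F3x4")
  a1 <- fit_model(aln, tree, "A1", frequencies = freqs,
                  restarts = config$restarts,
                  init = list(p0 = 0.75, p1 = 0.2, omega0 = 0.1),
                  maxit = 450, factr = 1e9)
  a2_init <- list(kappa = a1$kappa, p0 = a1$params$p0, p1 = a1$params$p1,
                  omega0 = a1$params$omega0)
  # two omega2 starting points: the likelihood in omega2 can be bimodal
  # (boundary optimum near 1 vs a strong-selection optimum), so a start on
  # each side keeps single-pass fits out of the wrong basin
  fits <- lapply(c(2, 50), function(w2_start)
    fit_model(aln, a1$tree, "A2", frequencies = freqs,
              restarts = config$restarts,
              fix_branch_lengths = config$reuse_null_lengths,
              fix_kappa = if (config$reuse_null_lengths) a1$kappa else NULL,
              init = c(a2_init, list(omega2 = w2_start)),
              maxit = 450, factr = 1e9))
  a2 <- fits[[which.max(vapply(fits, `[[`, 0, "lnL"))]]
  if (a2$lnL < a1$lnL) {
    # refit A2 from the exact null solution (omega2 at its boundary)
    a2b <- fit_model(aln, a1$tree, "A2", frequencies = freqs, restarts = 1,
                     fix_branch_lengths = TRUE, fix_kappa = a1$kappa,
                     init = c(a2_init, list(omega2 = 1 + 1e-6)),
                     maxit = 450, factr = 1e9)
    if (a2b$lnL > a2$lnL) a2 <- a2b
  }
  list(a1 = a1, a2 = a2)
}

#' Run the branch-site power / false-positive study
#'
#' For each replicate: simulate under the configured generating model, fit
#' branch-site models A1 and A2, test A1 vs A2 at `alpha`, and, when the
#' test is significant, run BEB and score flagged sites against the truth.
#' BEB confusion counts are pooled over replicates (micro-average);
#' per-replicate ratio averages are reported alongside.
#'
#' @param config A [power_config()].
#' @param seed Integer root seed; per-replicate seeds are derived
#'   deterministically so any replicate is reproducible in isolation.
#' @return Object of class `power_summary`: the test-level rate
#'   (`test_rate`: power for A2-generated, false-positive rate for
#'   A1-generated), per-threshold pooled BEB `power`, `accuracy` and `fpr`,
#'   counts of failed/excluded replicates, and a per-replicate data frame
#'   (`replicates`).
#' @export
run_power_study <- function(config, seed = 1) {
  stopifnot(inherits(config, "power_config"))
  template <- config$template
  tree <- config$tree
  if (is.null(tree))
    tree <- gstall_like_tree(seed, n_taxa = template$n_taxa,
                             template = template)
  study_tree <- scale_branches(tree, config$branch_scale)
  model <- template_model(template, config$generating_model)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  rep_seeds <- sample.int(.Machine$integer.max - 1, config$n_replicates)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  thr <- config$beb_thresholds
  pooled <- lapply(thr, function(t) list(tp = 0, fp = 0, n_true = 0,
                                         n_false = 0))
  names(pooled) <- paste0("p", thr * 100)
  rep_rows <- vector("list", config$n_replicates)
  per_rep_ratio <- lapply(thr, function(t)
    list(power = numeric(0), accuracy = numeric(0), fpr = numeric(0)))
  names(per_rep_ratio) <- names(pooled)
  n_failed <- 0L

  for (r in seq_len(config$n_replicates)) {
    sim <- simulate_alignment(study_tree, model, template$n_codons,
                              seed = rep_seeds[r])
    row <- data.frame(replicate = r, seed = rep_seeds[r], lnL_a1 = NA_real_,
                      lnL_a2 = NA_real_, two_delta = NA_real_,
                      p_value = NA_real_, significant = NA,
                      omega2_hat = NA_real_, failed = FALSE)
    res <- try({
      fits <- fit_branch_site_pair(sim$alignment, study_tree, config)
      test <- lrt(fits$a1, fits$a2)
      list(fits = fits, test = test)
    }, silent = TRUE)
    if (inherits(res, "try-error") || !res$fits$a1$converged ||
        !res$fits$a2$converged) {
      n_failed <- n_failed + 1L
      row$failed <- TRUE
      rep_rows[[r]] <- row
      next
    }
    row$lnL_a1 <- res$fits$a1$lnL
    row$lnL_a2 <- res$fits$a2$lnL
    row$two_delta <- res$test$two_delta
    row$p_value <- res$test$p_value
    row$significant <- res$test$p_value <= config$alpha
    row$omega2_hat <- res$fits$a2$params$omega2
    if (row$significant && config$run_beb) {
      beb <- beb_site_posteriors(sim$alignment, study_tree, res$fits$a2)
      for (ti in seq_along(thr)) {
        key <- names(pooled)[ti]
        flagged <- which(beb$positive_posterior > thr[ti])
        m <- site_detection_metrics(flagged, sim$true_classes)
        pooled[[key]]$tp <- pooled[[key]]$tp + m$tp
        pooled[[key]]$fp <- pooled[[key]]$fp + m$fp
        pooled[[key]]$n_true <- pooled[[key]]$n_true + m$n_true
        pooled[[key]]$n_false <- pooled[[key]]$n_false + m$n_false
        per_rep_ratio[[key]]$power <- c(per_rep_ratio[[key]]$power, m$power)
        if (!is.na(m$accuracy))
          per_rep_ratio[[key]]$accuracy <-
            c(per_rep_ratio[[key]]$accuracy, m$accuracy)
        per_rep_ratio[[key]]$fpr <- c(per_rep_ratio[[key]]$fpr, m$fpr)
      }
    }
    rep_rows[[r]] <- row
  }
  reps <- do.call(rbind, rep_rows)
  done <- reps[!reps$failed, , drop = FALSE]
  test_rate <- if (nrow(done)) mean(done$significant) else NA_real_

  beb_summary <- lapply(names(pooled), function(key) {
    cc <- pooled[[key]]
    list(
      power = if (cc$n_true > 0) cc$tp / cc$n_true else NA_real_,
      accuracy = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_,
      fpr = if (cc$n_false > 0) cc$fp / cc$n_false else NA_real_,
      counts = cc,
      mean_power = mean(per_rep_ratio[[key]]$power),
      mean_accuracy = mean(per_rep_ratio[[key]]$accuracy),
      mean_fpr = mean(per_rep_ratio[[key]]$fpr),
      per_replicate = per_rep_ratio[[key]])
  })
  names(beb_summary) <- names(pooled)

  structure(list(
    condition = list(generating_model = config$generating_model,
                     omega2 = config$omega2,
                     branch_scale = config$branch_scale,
                     n_taxa = template$n_taxa, n_codons = template$n_codons,
                     alpha = config$alpha),
    n_replicates = config$n_replicates,
    n_failed = n_failed,
    test_rate = test_rate,
    test_power = if (config$generating_model == "A2") test_rate else NA_real_,
    test_fpr = if (config$generating_model == "A1") test_rate else NA_real_,
    beb = beb_summary,
    replicates = reps,
    tree = tree,
    seed = seed
  ), class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("power study: generated under %s%s, branch scale %g\n",
              cond$generating_model,
              if (cond$generating_model == "A2")
                sprintf(" (omega2 = %g)", cond$omega2) else "",
              cond$branch_scale))
  cat(sprintf("  %d replicates (%d failed); LRT rate at alpha=%g: %.3f\n",
              x$n_replicates, x$n_failed, cond$alpha, x$test_rate))
  for (key in names(x$beb)) {
    b <- x$beb[[key]]
    if (!is.na(b$power) || !is.na(b$fpr))
      cat(sprintf("  BEB %s: power %.3f accuracy %s fpr %.4f\n", key,
                  b$power, ifelse(is.na(b$accuracy), "NA",
                                  sprintf("%.3f", b$accuracy)), b$fpr))
  }
  invisible(x)
}

#' Study profiles for the simulation grid
#'
#' The `fast` profile (12 taxa, 257 codons, 50 replicates) is the
#' desk-scale configuration used by the test suite and the acceptance
#' script; `full` mirrors the original study scale (31 taxa, 257 codons,
#' 100 replicates) and is a batch job.
#'
#' @param profile `"fast"` or `"full"`.
#' @return List with `template` (a [dataset_template()]) and
#'   `n_replicates`.
#' @export
study_profile <- function(profile = c("fast", "full")) {
  profile <- match.arg(profile)
  if (profile == "fast")
    list(template = dataset_template(n_taxa = 12, n_codons = 257),
         n_replicates = 50)
  else
    list(template = dataset_template(n_taxa = 31, n_codons = 257),
         n_replicates = 100)
}

#' Run the full branch-site simulation grid
#'
#' Reproduces the study's six conditions on one calibrated tree: the null
#' (A1-generated) false-positive rate at true and doubled branch lengths,
#' and the power of the A1-vs-A2 LRT for foreground omega2 of 4, 9 and 999
#' at true lengths plus omega2 = 9 at halved lengths. BEB site-detection
#' metrics are collected for the three scale-1 A2 conditions.
#'
#' @param seed Integer root seed (tree calibration and every replicate
#'   stream derive from it).
#' @param profile `"fast"` or `"full"` (see [study_profile()]).
#' @param n_replicates Override the profile's replicate count.
#' @return Named list of `power_summary` objects:
#'   `null`, `null_scale2`, `w2_4`, `w2_9`, `w2_9_half`, `w2_999`,
#'   plus `tree` (the calibrated tree).
#' @export
run_study_grid <- function(seed, profile = "fast", n_replicates = NULL) {
  prof <- study_profile(profile)
  if (is.null(n_replicates)) n_replicates <- prof$n_replicates
  template <- prof$template
  tree <- gstall_like_tree(seed, n_taxa = template$n_taxa,
                           template = template)
  run1 <- function(gen, omega2, scale, beb, cond_seed) {
    cfg <- power_config(gen, omega2 = omega2, n_replicates = n_replicates,
                        branch_scale = scale, template = template,
                        tree = tree, run_beb = beb)
    run_power_study(cfg, seed = cond_seed)
  }
  # distinct, deterministic sub-seeds per condition
  sub <- function(k) as.integer((seed + 1000003 * k) %% .Machine$integer.max)
  list(null = run1("A1", 9, 1, FALSE, sub(1)),
       null_scale2 = run1("A1", 9, 2, FALSE, sub(2)),
       w2_4 = run1("A2", 4, 1, TRUE, sub(3)),
       w2_9 = run1("A2", 9, 1, TRUE, sub(4)),
       w2_9_half = run1("A2", 9, 0.5, FALSE, sub(5)),
       w2_999 = run1("A2", 999, 1, TRUE, sub(6)),
       tree = tree)
}
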