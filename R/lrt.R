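# Likelihood-ratio tests between registered nested model pairs.
# 2*delta = 2[lnL(alt) - lnL(null)] is referred to a chi-square with df equal
# to the difference in free parameter counts; the plain chi-square is used
# throughout (no boundary mixture correction), the convention of the
# standard branch-site testing workflow.

# registered nested pairs; df as a function of the tree
NESTED_PAIRS <- list(
  "M1a|M2a" = function(tree) 2L,
  "M7|M8" = function(tree) 2L,
  "M8a|M8" = function(tree) 1L,
  "branch0|branch1" = function(tree) n_branches(tree) - 1L,
  "branch0|branch2_strict" = function(tree) 1L,
  "branch2_relaxed|branch2_strict" = function(tree) 1L,
  "A1|A2" = function(tree) 1L
)

#' Likelihood-ratio test of two nested codon model fits
#'
#' @param null_fit,alt_fit `codon_fit` objects forming a registered nested
#'   pair (M1a in M2a, M7 in M8, M8a in M8, branch0 in branch1, branch0 in
#'   strict branch model 2, relaxed in strict branch model 2, A1 in A2).
#' @return Object of class `lrt_result`: `null_model`, `alt_model`,
#'   `two_delta` (clamped at 0; small negative values from optimizer noise
#'   are clamped with a warning), `df`, `p_value`.
#' @export
lrt <- function(null_fit, alt_fit) {
  key <- paste(null_fit$model, alt_fit$model, sep = "|")
  if (is.null(NESTED_PAIRS[[key]]))
    stop("models '", null_fit$model, "' and '", alt_fit$model,
         "' are not a registered nested pair")
  df <- NESTED_PAIRS[[key]](null_fit$tree)
  two_delta <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (two_delta < 0) {
    if (two_delta < -1e-4)
      warning("negative 2*delta (", signif(two_delta, 3),
              ") clamped to 0; optimizer noise or unconverged fit")
    two_delta <- 0
  }
  structure(list(null_model = null_fit$model, alt_model = alt_fit$model,
                 two_delta = two_delta, df = df,
                 p_value = stats::pchisq(two_delta, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s (df = %d): 2*delta = %.4g, P = %.4g\n",
              x$null_model, x$alt_model, x$df, x$two_delta, x$p_value))
  invisible(x)
}
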