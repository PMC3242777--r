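# Genetic-code tables shared by every module. Universal nuclear code,
# 61 sense codons; stop codons are never valid states.

NUC <- c("T", "C", "A", "G")

#' @noRd
codon_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
    # order: position 1 slowest, position 3 fastest (TTT, TTC, TTA, ...)
    codons <- apply(expand.grid(p3 = NUC, p2 = NUC, p1 = NUC)[, 3:1], 1, paste0,
                    collapse = "")
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    stopifnot(!anyNA(aa))
    sense <- aa != "*"
    tab <- list(
      codons64 = codons,
      aa64 = aa,
      codons = codons[sense],
      aa = aa[sense]
    )
    tab$index <- stats::setNames(seq_along(tab$codons), tab$codons)
    cache <<- tab
    tab
  }
})

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons, in the fixed internal
#'   order used throughout the package (first codon position varying
#'   slowest, T < C < A < G).
#' @export
sense_codons <- function() codon_table()$codons

#' @noRd
codon_aa <- function() codon_table()$aa

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# 61 x 61 integer matrix classifying ordered sense-codon pairs:
# 0 = identical or >1 nucleotide difference, 1 = synonymous transition,
# 2 = synonymous transversion, 3 = nonsynonymous transition,
# 4 = nonsynonymous transversion.
#' @noRd
codon_pair_type <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tab <- codon_table()
    n <- length(tab$codons)
    splits <- strsplit(tab$codons, "")
    type <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      ci <- splits[[i]]
      for (j in seq_len(n)) {
        if (i == j) next
        cj <- splits[[j]]
        diff <- which(ci != cj)
        if (length(diff) != 1L) next
        ts <- is_transition(ci[diff], cj[diff])
        syn <- tab$aa[i] == tab$aa[j]
        type[i, j] <- if (syn) (if (ts) 1L else 2L) else (if (ts) 3L else 4L)
      }
    }
    cache <<- type
    type
  }
})

#' Translate codon state indices to amino acids
#' @noRd
translate_codes <- function(codes) {
  aa <- codon_aa()
  out <- rep(NA_character_, length(codes))
  ok <- !is.na(codes)
  out[ok] <- aa[codes[ok]]
  out
}
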