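# Pairwise divergence statistics: protein identity and Nei-Gojobori (1986)
# synonymous / nonsynonymous divergence with Jukes-Cantor correction.
# These support the saturation assessment that precedes model fitting:
# synonymous divergence (kS) well above ~1 signals multiple hits at
# synonymous sites and motivates caution with likelihood-ratio tests.

#' Pairwise protein identity of two aligned amino-acid sequences
#'
#' Identity is counted over columns where neither sequence has a gap
#' (pairwise deletion), as the fraction of identical residue pairs.
#'
#' @param seq_a,seq_b Aligned amino-acid strings of equal length (gaps `-`
#'   allowed).
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_protein_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a != "-" & b != "-" & a != "X" & b != "X"
  if (!any(keep)) stop("no comparable (non-gap) positions")
  mean(a[keep] == b[keep])
}

# Per-codon synonymous site counts and per-pair pathway-averaged difference
# counts, cached as 61-vectors / 61x61 matrices so pairwise scans are table
# lookups.
ng86_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tab <- codon_table()
    n <- length(tab$codons)
    splits <- strsplit(tab$codons, "")
    full_aa <- stats::setNames(unname(Biostrings::GENETIC_CODE[tab$codons64]),
                               tab$codons64)
    # synonymous site count per codon: at each position, fraction of the 3
    # possible changes that are synonymous; changes to stop codons count as
    # nonsynonymous (standard NG86 site counting)
    syn_sites <- numeric(n)
    for (i in seq_len(n)) {
      ci <- splits[[i]]
      s <- 0
      for (pos in 1:3) for (nt in setdiff(NUC, ci[pos])) {
        cj <- ci; cj[pos] <- nt
        cjs <- paste0(cj, collapse = "")
        if (full_aa[cjs] != "*" && full_aa[cjs] == tab$aa[i]) s <- s + 1 / 3
      }
      syn_sites[i] <- s
    }
    # pathway-averaged synonymous / nonsynonymous differences per codon pair;
    # minimal mutational pathways weighted equally, pathways through stop
    # codons excluded (renormalized)
    sd <- matrix(0, n, n); nd <- matrix(0, n, n)
    step_counts <- function(from, to) {
      # one nucleotide apart, both sense
      if (full_aa[from] == full_aa[to]) c(1, 0) else c(0, 1)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        ci <- splits[[i]]; cj <- splits[[j]]
        diff <- which(ci != cj)
        k <- length(diff)
        if (k == 0) next
        perms <- switch(k, list(diff),
                        list(diff, rev(diff)),
                        {
                          p <- list()
                          for (ord in list(c(1,2,3), c(1,3,2), c(2,1,3),
                                           c(2,3,1), c(3,1,2), c(3,2,1)))
                            p[[length(p) + 1]] <- diff[ord]
                          p
                        })
        acc <- c(0, 0); nvalid <- 0
        for (pth in perms) {
          cur <- ci; from <- paste0(cur, collapse = "")
          tot <- c(0, 0); ok <- TRUE
          for (pos in pth) {
            cur[pos] <- cj[pos]
            to <- paste0(cur, collapse = "")
            if (full_aa[to] == "*") { ok <- FALSE; break }
            tot <- tot + step_counts(from, to)
            from <- to
          }
          if (ok) { acc <- acc + tot; nvalid <- nvalid + 1 }
        }
        if (nvalid == 0) {
          # all minimal pathways blocked by stops; fall back to counting each
          # differing position independently against the direct amino acids
          acc <- c(0, k); nvalid <- 1
        }
        sd[i, j] <- sd[j, i] <- acc[1] / nvalid
        nd[i, j] <- nd[j, i] <- acc[2] / nvalid
      }
    }
    cache <<- list(syn_sites = syn_sites, sd = sd, nd = nd)
    cache
  }
})

#' Nei-Gojobori (1986) pairwise synonymous and nonsynonymous divergence
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence, averages
#' differences over all minimal mutational pathways with equal weight
#' (pathways through stop codons excluded), and applies the Jukes-Cantor
#' multiple-hit correction `d = -3/4 log(1 - 4p/3)`. Codon columns where
#' either sequence has a gap or ambiguity are skipped (pairwise deletion).
#' Pairs whose proportion of differences reaches the correction's domain
#' boundary (`p >= 3/4`) are flagged saturated with `NA` distance.
#'
#' @param seq_a,seq_b Equal-length in-frame codon sequences (character
#'   strings) or a two-taxon slice of a [codon_alignment()].
#' @return A list of class `pairwise_divergence`: `ks`, `ka` (per-site
#'   corrected distances, `NA` when undefined), `S`, `N` (site counts),
#'   `ps`, `pn` (uncorrected proportions), `saturated` (logical, per
#'   statistic) and `n_codons_used`.
#' @export
ks_ng86 <- function(seq_a, seq_b) {
  aln <- codon_alignment(c(a = seq_a, b = seq_b))
  ks_ng86_codes(aln$codes[1, ], aln$codes[2, ])
}

# internal: operate on codon state indices (NA = skip)
ks_ng86_codes <- function(x, y) {
  tabs <- ng86_tables()
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop("no comparable codon sites")
  S <- (sum(tabs$syn_sites[x]) + sum(tabs$syn_sites[y])) / 2
  N <- 3 * length(x) - S
  Sd <- sum(tabs$sd[cbind(x, y)])
  Nd <- sum(tabs$nd[cbind(x, y)])
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- if (is.na(ps)) NA_real_ else jc(min(ps, 1))
  ka <- if (is.na(pn)) NA_real_ else jc(min(pn, 1))
  structure(list(
    ks = ks, ka = ka, S = S, N = N, ps = ps, pn = pn,
    saturated = c(ks = !is.na(ps) && ps >= 0.75,
                  ka = !is.na(pn) && pn >= 0.75),
    n_codons_used = length(x)
  ), class = "pairwise_divergence")
}

#' All-pairs synonymous/nonsynonymous divergence table for an alignment
#'
#' @param aln A [codon_alignment()].
#' @return Data frame with one row per unordered taxon pair: `taxon_a`,
#'   `taxon_b`, `ks`, `ka`, `saturated_ks`, `saturated_ka`.
#' @export
pairwise_divergence_table <- function(aln) {
  n <- length(aln$taxa)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- ks_ng86_codes(aln$codes[i, ], aln$codes[j, ])
    rows[[length(rows) + 1]] <- data.frame(
      taxon_a = aln$taxa[i], taxon_b = aln$taxa[j],
      ks = d$ks, ka = d$ka,
      saturated_ks = unname(d$saturated["ks"]),
      saturated_ka = unname(d$saturated["ka"]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Translate a codon alignment to amino acids
#'
#' @param aln A [codon_alignment()].
#' @return Named character vector of aligned amino-acid sequences (missing
#'   codons as `-`).
#' @export
translate_alignment <- function(aln) {
  aa <- codon_aa()
  apply(aln$codes, 1, function(row)
    paste0(ifelse(is.na(row), "-", aa[row]), collapse = ""))
}
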