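# Codon alignments: construction, validation, FASTA / sequential PHYLIP I/O.

#' Construct a codon alignment
#'
#' A codon alignment stores aligned in-frame coding sequences as states over
#' the 61 sense codons. Gap codons (`---`) and codons containing gaps or
#' IUPAC ambiguity codes are kept as missing states and are marginalized in
#' likelihood computations and skipped in pairwise statistics.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (equal lengths, length divisible by 3).
#' @return An object of class `codon_alignment` with elements `taxa`
#'   (character), `codes` (integer matrix, taxa x codon sites; `NA` marks
#'   gap/ambiguous codons) and `n_codons`.
#' @export
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  taxa <- names(sequences)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  sequences <- toupper(gsub("\\s", "", sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (lens[1] %% 3L != 0L)
    stop("frame error: alignment length ", lens[1], " is not divisible by 3")
  n_codons <- unname(lens[1] %/% 3L)
  tab <- codon_table()
  codes <- matrix(NA_integer_, length(taxa), n_codons,
                  dimnames = list(taxa, NULL))
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_along(taxa)) {
    cods <- substring(sequences[i], starts, starts + 2L)
    idx <- tab$index[cods]
    bad_stop <- which(cods %in% stops)
    if (length(bad_stop))
      stop("internal stop codon ", cods[bad_stop[1]], " in taxon '", taxa[i],
           "' at codon site ", bad_stop[1])
    # anything not a sense codon (gap or ambiguity) is a missing state
    codes[i, ] <- unname(idx)
  }
  structure(list(taxa = taxa, codes = codes, n_codons = n_codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$taxa), "taxa x", x$n_codons, "codons\n")
  invisible(x)
}

#' Rebuild nucleotide sequences from a codon alignment
#' @param aln A `codon_alignment`.
#' @return Named character vector of aligned nucleotide sequences; missing
#'   codon states are written as `---`.
#' @export
alignment_sequences <- function(aln) {
  cods <- codon_table()$codons
  apply(aln$codes, 1, function(row) {
    s <- ifelse(is.na(row), "---", cods[row])
    paste0(s, collapse = "")
  })
}

#' Read a codon alignment from FASTA or sequential PHYLIP
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"` (sequential, relaxed whitespace-
#'   delimited names).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(set), names(set))
    # keep only the first whitespace-delimited token of each header
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else {
    seqs <- read_phylip_sequential(path)
  }
  codon_alignment(seqs)
}

read_phylip_sequential <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L) stop("malformed PHYLIP header")
  ntax <- suppressWarnings(as.integer(hdr[1]))
  nchar_aln <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(ntax) || is.na(nchar_aln)) stop("malformed PHYLIP header")
  body <- paste(lines[-1], collapse = "\n")
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  seqs <- character(0); labels <- character(0)
  i <- 1L
  while (length(labels) < ntax && i <= length(toks)) {
    labels <- c(labels, toks[i]); i <- i + 1L
    acc <- ""
    while (nchar(acc) < nchar_aln && i <= length(toks)) {
      acc <- paste0(acc, toks[i]); i <- i + 1L
    }
    seqs <- c(seqs, acc)
  }
  if (length(labels) != ntax || any(nchar(seqs) != nchar_aln))
    stop("PHYLIP file does not match its header (", ntax, " x ", nchar_aln, ")")
  stats::setNames(seqs, labels)
}

#' Write a codon alignment
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_codon_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- alignment_sequences(aln)
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(" %d %d", length(seqs), nchar(seqs[1])), con)
    writeLines(paste(format(names(seqs), width = 12), seqs), con)
  }
  invisible(path)
}
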