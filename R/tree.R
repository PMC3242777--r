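# Phylogenetic trees with foreground branch flags. Newick parsing/writing is
# delegated to ape; branch labels of the form "#1" (codeml convention) mark
# foreground lineages for branch and branch-site models.

#' Construct a tree with foreground flags
#'
#' @param phylo An `ape::phylo` object (interpreted as unrooted; a basal
#'   multifurcation is the standard unrooted representation).
#' @param foreground Logical vector along `phylo$edge` rows flagging
#'   foreground branches (default none).
#' @return Object of class `codon_tree`: list with `phylo` and `foreground`.
#' @export
codon_tree <- function(phylo, foreground = NULL) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape 'phylo' object")
  ne <- nrow(phylo$edge)
  if (is.null(phylo$edge.length)) stop("tree must have branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative branch length in tree")
  if (is.null(foreground)) foreground <- rep(FALSE, ne)
  if (length(foreground) != ne) stop("foreground flag length != branch count")
  structure(list(phylo = phylo, foreground = as.logical(foreground)),
            class = "codon_tree")
}

#' @export
print.codon_tree <- function(x, ...) {
  cat("codon tree:", length(x$phylo$tip.label), "taxa,",
      nrow(x$phylo$edge), "branches,", sum(x$foreground),
      "foreground-flagged\n")
  invisible(x)
}

#' Number of branches of a tree
#' @param tree A `codon_tree`.
#' @return Integer branch count (2n-3 for a fully resolved unrooted tree of
#'   n taxa).
#' @export
n_branches <- function(tree) nrow(tree$phylo$edge)

#' Read a Newick tree with optional codeml-style foreground labels
#'
#' Branch labels `#1` (optionally preceded by whitespace) after a tip name
#' or a clade's closing parenthesis mark the branch leading to that node as
#' foreground. The tree is treated as unrooted; a rooted binary Newick is
#' unrooted on reading.
#'
#' @param path Path to a Newick file (or a literal Newick string).
#' @return A [codon_tree()].
#' @export
read_tree <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "") else path
  txt <- gsub("\\s+", "", txt)
  # protect "#1" marks by rewriting them into node labels ape will keep
  txt <- gsub("#(\\d+)", "__FG\\1__", txt)
  phylo <- ape::read.tree(text = txt)
  if (is.null(phylo)) stop("could not parse Newick input")
  # unroot first so node numbering is final before flags are extracted
  if (ape::is.rooted(phylo) && phylo$Nnode > 1)
    phylo <- ape::unroot(phylo)
  flag_from_label <- function(labels) grepl("__FG\\d+__$", labels)
  strip <- function(labels) sub("__FG\\d+__$", "", labels)
  tipflag <- flag_from_label(phylo$tip.label)
  phylo$tip.label <- strip(phylo$tip.label)
  nodeflag <- rep(FALSE, phylo$Nnode)
  if (!is.null(phylo$node.label)) {
    nodeflag <- flag_from_label(phylo$node.label)
    phylo$node.label <- strip(phylo$node.label)
    if (all(phylo$node.label == "")) phylo$node.label <- NULL
  }
  ntip <- length(phylo$tip.label)
  flagged_nodes <- c(which(tipflag), ntip + which(nodeflag))
  if (is.null(phylo$edge.length))
    stop("tree must contain branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative branch length in tree")
  fg <- phylo$edge[, 2] %in% flagged_nodes
  codon_tree(phylo, fg)
}

#' Write a tree to Newick with `#1` foreground marks
#' @param tree A `codon_tree`.
#' @param path Output file path, or `NULL` to return the Newick string.
#' @export
write_tree <- function(tree, path = NULL) {
  phylo <- tree$phylo
  ntip <- length(phylo$tip.label)
  fg_nodes <- phylo$edge[tree$foreground, 2]
  if (length(fg_nodes)) {
    tipsel <- fg_nodes[fg_nodes <= ntip]
    phylo$tip.label[tipsel] <- paste0(phylo$tip.label[tipsel], "__FG1__")
    nodesel <- fg_nodes[fg_nodes > ntip] - ntip
    if (length(nodesel)) {
      if (is.null(phylo$node.label)) phylo$node.label <- rep("", phylo$Nnode)
      phylo$node.label[nodesel] <- paste0(phylo$node.label[nodesel], "__FG1__")
    }
  }
  txt <- ape::write.tree(phylo)
  txt <- gsub("__FG1__", "#1", txt, fixed = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Scale all branch lengths of a tree
#'
#' Used by the simulation study to halve or double divergence while keeping
#' topology and foreground flags.
#'
#' @param tree A `codon_tree`.
#' @param factor Positive scale factor.
#' @return The scaled `codon_tree`.
#' @export
scale_branches <- function(tree, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a positive scalar")
  tree$phylo$edge.length <- tree$phylo$edge.length * factor
  tree
}

#' Set the foreground branch by its index
#' @param tree A `codon_tree`.
#' @param edge Integer index (row of `tree$phylo$edge`) to flag; all other
#'   flags are cleared.
#' @export
set_foreground <- function(tree, edge) {
  fg <- rep(FALSE, n_branches(tree))
  fg[edge] <- TRUE
  tree$foreground <- fg
  tree
}

# internal: check tree/alignment taxon agreement
check_taxa <- function(aln, tree) {
  if (!setequal(aln$taxa, tree$phylo$tip.label))
    stop("tree leaves and alignment taxa do not match")
  invisible(TRUE)
}
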