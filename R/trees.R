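# Balanced-tree generation and Newick I/O (thin layer over ape).

#' Generate a balanced binary tree with uniform branch lengths
#'
#' Builds a rooted, complete balanced binary tree on `nTaxa` leaves in which
#' every edge, including the two edges descending from the root, has length
#' `branchLength`. Branch lengths are divergences per site, so any two
#' adjacent nodes are separated by `branchLength` and the two leaves of a
#' cherry by twice that. Leaf labels are `t1 ... tn`, assigned
#' deterministically.
#'
#' @param nTaxa number of leaves; must be a power of two, >= 2.
#' @param branchLength positive edge length shared by all edges.
#' @return An ape `phylo` object with `2 * nTaxa - 2` edges.
#' @export
#' @examples
#' tr <- makeBalancedTree(16, 0.04)
#' ape::Ntip(tr)     # 16
#' ape::Nedge(tr)    # 30
makeBalancedTree <- function(nTaxa, branchLength) {
  if (length(nTaxa) != 1L || nTaxa < 2 || nTaxa != as.integer(nTaxa) ||
      bitwAnd(as.integer(nTaxa), as.integer(nTaxa) - 1L) != 0L) {
    stop("nTaxa must be a power of two >= 2, got ", nTaxa)
  }
  if (length(branchLength) != 1L || !is.finite(branchLength) ||
      branchLength <= 0) {
    stop("branchLength must be a positive number, got ", branchLength)
  }
  tree <- ape::stree(as.integer(nTaxa), type = "balanced")
  tree$edge.length <- rep(branchLength, nrow(tree$edge))
  tree
}

#' Write and read trees in Newick format
#'
#' Plain-label Newick with branch lengths; writing then reading reproduces
#' topology and edge lengths.
#'
#' @param tree an ape `phylo` object with edge lengths.
#' @param path file path.
#' @return `readNewick` returns a `phylo`; `writeNewick` returns `path`
#'   invisibly.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .checkNewickSyntax(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  tree
}

# Cheap structural pre-check so malformed input is rejected with the
# character position of the failure (ape's own errors are less specific).
.checkNewickSyntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of input")
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed Newick: missing terminating ';'")
  invisible(TRUE)
}
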