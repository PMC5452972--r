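# Phylogenetic likelihood engine: spectral transition probabilities for
# reversible processes and a site-vectorized Felsenstein pruning pass with
# per-node scaling. Shared by the codon (FEL1) and amino-acid (gamma
# categories) inference paths.

# For a reversible Q with stationary pi, exp(Qt) is computed from the
# eigendecomposition of the symmetrized matrix B = D^{1/2} Q D^{-1/2}.
# Returns a closure P(t); results are cached per distinct t, so balanced
# trees (one edge length) cost a single reconstruction.
.transitionFactory <- function(Q, pi) {
  if (is(Q, "RateMatrix")) { pi <- Q@stationary; Q <- Q@Q }
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors
  lam <- eig$values
  n <- nrow(Q)
  Ud <- (1 / d) * U            # D^{-1/2} U  (row scaling)
  Vt <- t(d * U)               # U^T D^{1/2}
  cache <- new.env(parent = emptyenv())
  function(t) {
    key <- format(t, digits = 15)
    P <- cache[[key]]
    if (!is.null(P)) return(P)
    P <- Ud %*% (exp(lam * t) * Vt)
    P[P < 0] <- 0
    P <- P / rowSums(P)
    cache[[key]] <- P
    P
  }
}

# Map state characters to integer indices; NA marks missing data.
.encodeStates <- function(m, alphabet) {
  idx <- match(m, alphabet)
  matrix(idx, nrow(m), ncol(m), dimnames = dimnames(m))
}

# Site-vectorized pruning. stateIdx: nTaxa x nSites integer matrix, rows in
# tree tip-label order, NA = missing (partial likelihood of ones). Pfun(t)
# returns the transition matrix for an edge of length t. rootFreq is either
# a vector (shared across sites) or an nStates x nSites matrix. Returns the
# per-site log-likelihood vector.
.pruneLogLik <- function(stateIdx, tree, Pfun, rootFreq, nStates) {
  nTip <- length(tree$tip.label)
  nSitesHere <- ncol(stateIdx)
  if (nTip == 1L) {  # degenerate: likelihood is the root prior of the state
    rf <- if (is.matrix(rootFreq)) rootFreq else
      matrix(rootFreq, nStates, nSitesHere)
    return(log(rf[cbind(stateIdx[1L, ], seq_len(nSitesHere))]))
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  L <- vector("list", tr$Nnode)
  logScale <- numeric(nSitesHere)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    P <- Pfun(elen[e])
    if (child <= nTip) {
      idx <- stateIdx[child, ]
      miss <- is.na(idx)
      if (any(miss)) idx[miss] <- 1L
      contrib <- P[, idx, drop = FALSE]
      if (any(miss)) contrib[, miss] <- 1
    } else {
      cl <- L[[child - nTip]]
      cmax <- apply(cl, 2L, max)
      if (any(!is.finite(cmax)) || any(cmax <= 0))
        stop("non-finite partial likelihood at edge ", e,
             " (node ", child, ")")
      logScale <- logScale + log(cmax)
      contrib <- P %*% (cl * rep(1 / cmax, each = nStates))
      L[child - nTip] <- list(NULL)  # free memory without shifting indices
    }
    slot <- parent - nTip
    L[[slot]] <- if (is.null(L[[slot]])) contrib else L[[slot]] * contrib
  }
  rootL <- L[[1L]]  # root node is nTip + 1 in ape numbering
  lik <- if (is.matrix(rootFreq)) colSums(rootFreq * rootL)
         else colSums(rootFreq * rootL)
  log(lik) + logScale
}

#' Phylogenetic log-likelihood of one codon column
#'
#' Log-likelihood of a single alignment column under the site-specific
#' Muse-Gaut model with rates (`dN`, `dS`), computed by postorder pruning
#' with the model's stationary distribution at the root. Numerical
#' underflow is handled by per-node scaling.
#'
#' @param column character vector of codon states, named by taxon or given
#'   in the order of `tree$tip.label`.
#' @param tree ape `phylo` with branch lengths.
#' @param dN nonsynonymous rate (>= 0).
#' @param dS synonymous rate (> 0).
#' @param codonFreqs equilibrium codon frequencies (default uniform).
#' @return Finite log-likelihood value.
#' @export
#' @examples
#' tr <- makeBalancedTree(4, 0.2)
#' siteLogLik(setNames(rep("ATG", 4), tr$tip.label), tr, dN = 0.5, dS = 1)
siteLogLik <- function(column, tree, dN, dS = 1, codonFreqs = NULL) {
  if (!is.null(names(column))) {
    if (!setequal(names(column), tree$tip.label))
      stop("column names do not match tree tip labels")
    column <- column[tree$tip.label]
  } else if (length(column) != length(tree$tip.label)) {
    stop("column length must equal the number of tips")
  }
  rm <- mg94Matrix(dN, dS, codonFreqs)
  Pfun <- .transitionFactory(rm)
  stateIdx <- matrix(match(column, .SENSE_CODONS), ncol = 1L)
  if (anyNA(stateIdx)) stop("column contains non-sense-codon states")
  as.numeric(.pruneLogLik(stateIdx, tree, Pfun, rm@stationary, .NCODON))
}
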