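# One-rate fixed-effects likelihood (FEL1): per-site maximum-likelihood dN
# with the synonymous rate fixed at 1 and branch lengths taken as given.
# Optimization is a coarse geometric grid shared by all sites (so each
# candidate costs one site-vectorized pruning pass), followed by a local
# 9-point geometric refinement around each site's bracket (vectorized by
# grouping sites with the same bracket) and a parabolic polish in log-dN.

#' Per-site dN/dS by one-rate fixed-effects likelihood
#'
#' Fits one nonsynonymous rate per site under the site-specific Muse-Gaut
#' model with `dS = 1` shared by all sites and tree branch lengths taken
#' as given, then applies the invariant-site rule: every site whose
#' translated column contains a single residue state (synonymous-only
#' variation included) is assigned dN/dS = 0, since with a shared
#' nonzero synonymous rate a fully conserved site carries no evidence of
#' nonsynonymous change.
#'
#' @param aln a `CodonAlignment`; taxa must match the tree's tip labels.
#' @param tree ape `phylo` with branch lengths.
#' @param codonFreqs equilibrium codon frequencies (default uniform).
#' @param dnMax upper bound of the dN search interval (default 10).
#' @param nGrid number of coarse geometric grid points on
#'   `[1e-4, dnMax]`.
#' @param refine logical; run the local refinement stage (default TRUE).
#' @return A `RateEstimates` with `scoreKind = "dnds"`,
#'   `normalization = "raw"`. `estimateDetails()` carries per-site
#'   log-likelihoods, the invariant-site flags, and flags for sites whose
#'   maximum sits at `dnMax`.
#' @export
#' @examples
#' set.seed(11)
#' tr <- makeBalancedTree(16, 0.3)
#' prof <- drawProfiles("constant_dS", 20)
#' fit <- fel1Fit(simulateAlignment(tr, prof), tr)
#' head(scores(fit))
fel1Fit <- function(aln, tree, codonFreqs = NULL, dnMax = 10,
                    nGrid = 48, refine = TRUE) {
  stopifnot(is(aln, "CodonAlignment"), inherits(tree, "phylo"))
  if (!setequal(taxonNames(aln), tree$tip.label))
    stop("alignment taxa and tree tip labels do not match")
  m <- aln@codons[tree$tip.label, , drop = FALSE]
  nS <- ncol(m)
  resid <- matrix(translateCodons(m), nrow(m), ncol(m))
  invariant <- apply(resid, 2L, function(col) length(unique(col)) == 1L)
  stateIdx <- .encodeStates(m, .SENSE_CODONS)

  parts <- .mg94Parts(codonFreqs)
  evalCandidate <- function(dn, cols) {
    rm <- .mg94FromParts(dn, 1, parts)
    Pf <- .transitionFactory(rm)
    .pruneLogLik(stateIdx[, cols, drop = FALSE], tree, Pf,
                 rm@stationary, .NCODON)
  }

  dnHat <- numeric(nS)
  logLik <- rep(NA_real_, nS)
  atBound <- logical(nS)
  varSites <- which(!invariant)

  if (length(varSites) > 0L) {
    grid <- exp(seq(log(1e-4), log(dnMax), length.out = nGrid))
    llGrid <- matrix(NA_real_, nGrid, length(varSites))
    for (g in seq_len(nGrid))
      llGrid[g, ] <- evalCandidate(grid[g], varSites)
    best <- max.col(t(llGrid), ties.method = "first")

    # per-site evaluated points: start from the coarse grid
    ptsX <- lapply(seq_along(varSites), function(i) log(grid))
    ptsY <- lapply(seq_along(varSites), function(i) llGrid[, i])

    if (refine) {
      for (g in sort(unique(best))) {
        sub <- which(best == g)
        lo <- grid[max(g - 1L, 1L)]
        hi <- grid[min(g + 1L, nGrid)]
        local <- exp(seq(log(lo), log(hi), length.out = 9L))[2:8]
        for (dn in local) {
          ll <- evalCandidate(dn, varSites[sub])
          for (j in seq_along(sub)) {
            ptsX[[sub[j]]] <- c(ptsX[[sub[j]]], log(dn))
            ptsY[[sub[j]]] <- c(ptsY[[sub[j]]], ll[j])
          }
        }
      }
    }

    for (i in seq_along(varSites)) {
      ord <- order(ptsX[[i]])
      x <- ptsX[[i]][ord]; y <- ptsY[[i]][ord]
      k <- which.max(y)
      if (k == 1L || k == length(x)) {
        est <- exp(x[k])
      } else {
        est <- exp(.parabolicVertex(x[k - 1L], x[k], x[k + 1L],
                                    y[k - 1L], y[k], y[k + 1L]))
      }
      s <- varSites[i]
      dnHat[s] <- min(est, dnMax)
      logLik[s] <- max(y)
      atBound[s] <- best[i] == nGrid
    }
    if (any(atBound))
      warning(sum(atBound), " site(s) reached the dN upper bound ", dnMax)
  }

  if (any(invariant)) {
    inv <- which(invariant)
    logLik[inv] <- evalCandidate(0, inv)
    dnHat[inv] <- 0
  }

  new("RateEstimates", scores = dnHat, scoreKind = "dnds",
      normalization = "raw",
      details = list(logLik = logLik, invariant = invariant,
                     dnMaxHit = atBound, dS = 1))
}

# Vertex of the parabola through three points, clamped to [x1, x3].
.parabolicVertex <- function(x1, x2, x3, y1, y2, y3) {
  num <- (x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)
  den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (abs(den) < 1e-12 * max(abs(num), 1)) return(x2)
  v <- x2 - 0.5 * num / den
  min(max(v, x1), x3)
}
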