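# Synthetic-data engine: per-site rate profile draws under the study
# regimes, sequence evolution along trees, and grid materialization.

# Deterministic per-replicate seed derivation (counter-based); keeps every
# derived seed inside 32-bit integer range.
.deriveSeed <- function(masterSeed, cellIndex, replicate) {
  base <- (abs(masterSeed) %% 2147483647) * 48271 +
    cellIndex * 69621 + replicate * 16807
  as.integer(base %% 2147483647)
}

# Default study parameters for the profile-drawing regimes.
.profileDefaults <- function() {
  list(
    dnMin = 0.1, dnMax = 1.6,          # uniform dN (constant-dS regime)
    ratioMin = 0.1, ratioMax = 1.6,    # uniform dN/dS (variable-dS regime)
    dsMin = 0.5, dsMax = 2,            # uniform dS (variable-dS regime)
    gammaShape = 0.312, gammaRate = 1.027,  # HIV-1 integrase dN/dS gamma
    dirichletConc = 0.5,               # MutSel amino-acid target profiles
    nucFreqs = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
    codonBiasSd = 0.5                  # sd of synonymous fitness offsets
  )
}

#' Draw site-specific rate profiles for a simulation regime
#'
#' Regimes (defaults give the package's standard study conditions):
#' \describe{
#'   \item{constant_dS}{`dS = 1` at every site, `dN ~ U(0.1, 1.6)`.}
#'   \item{variable_dS}{`dN/dS ~ U(0.1, 1.6)`, `dS ~ U(0.5, 2)`,
#'     `dN = dS * (dN/dS)`.}
#'   \item{gamma}{`dN/dS ~ Gamma(shape, rate)` (defaults 0.312, 1.027, the
#'     HIV-1 integrase estimates), `dS = 1`.}
#'   \item{mutsel_neutral_syn}{Halpern-Bruno site profiles: per-site target
#'     amino-acid frequencies from a symmetric Dirichlet (concentration
#'     0.5) converted to codon fitnesses; synonymous codons share fitness.}
#'   \item{mutsel_codon_bias}{As above plus independent `N(0, 0.5)` fitness
#'     offsets per codon, making synonymous codons non-neutral.}
#' }
#' Draws consume the current R RNG stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param regime regime name (see above).
#' @param nSites number of codon sites.
#' @param params optional named list overriding individual defaults
#'   (`dnMin`, `dnMax`, `ratioMin`, `ratioMax`, `dsMin`, `dsMax`,
#'   `gammaShape`, `gammaRate`, `dirichletConc`, `nucFreqs`,
#'   `codonBiasSd`).
#' @return A `SiteRateProfile` (dN/dS regimes) or `MutSelProfile`
#'   (mutation-selection regimes).
#' @export
#' @examples
#' set.seed(1)
#' p <- drawProfiles("constant_dS", 10)
#' range(dNdS(p))
drawProfiles <- function(regime, nSites, params = list()) {
  if (!regime %in% .REGIMES)
    stop("unknown regime '", regime, "'; must be one of: ",
         paste(.REGIMES, collapse = ", "))
  p <- utils::modifyList(.profileDefaults(), params)
  if (regime == "constant_dS") {
    return(siteRateProfile(dN = runif(nSites, p$dnMin, p$dnMax), dS = 1))
  }
  if (regime == "variable_dS") {
    ratio <- runif(nSites, p$ratioMin, p$ratioMax)
    dsVal <- runif(nSites, p$dsMin, p$dsMax)
    return(siteRateProfile(dN = dsVal * ratio, dS = dsVal))
  }
  if (regime == "gamma") {
    ratio <- rgamma(nSites, shape = p$gammaShape, rate = p$gammaRate)
    return(siteRateProfile(dN = ratio, dS = 1))
  }
  # MutSel regimes: Dirichlet amino-acid targets -> codon fitnesses
  mut <- mutationMatrix(p$nucFreqs)
  aaOfCodon <- .CODON_AA[.SENSE_CODONS]
  fit <- matrix(0, nSites, .NCODON, dimnames = list(NULL, .SENSE_CODONS))
  for (k in seq_len(nSites)) {
    g <- rgamma(20L, shape = p$dirichletConc, rate = 1)
    aaFreq <- setNames(g / sum(g), .AA_ORDER)
    f <- log(pmax(aaFreq[aaOfCodon], 1e-12))
    if (regime == "mutsel_codon_bias")
      f <- f + rnorm(.NCODON, sd = p$codonBiasSd)
    fit[k, ] <- f
  }
  mutSelProfile(fit, mut)
}

#' True per-site dN/dS of a profile
#'
#' For dN/dS-model profiles this is the simulation parameter itself; for
#' mutation-selection profiles it is the expected dN/dS implied by each
#' site's scaled selection coefficients (\code{\link{expectedDnDs}}).
#'
#' @param profile a `SiteRateProfile` or `MutSelProfile`.
#' @return Numeric vector of per-site dN/dS values.
#' @export
trueDnDs <- function(profile) {
  if (is(profile, "SiteRateProfile")) return(dNdS(profile))
  if (is(profile, "MutSelProfile")) {
    return(vapply(seq_len(nSites(profile)),
                  function(k) expectedDnDs(profile@fitness[k, ],
                                           profile@mutation),
                  numeric(1)))
  }
  stop("profile must be a SiteRateProfile or MutSelProfile")
}

# Exact grouping of a list of RateMatrix objects into identical-Q groups:
# a numeric hash narrows candidates, identical() confirms, so distinct
# matrices are never merged.
.groupModels <- function(models) {
  w <- rep_len(c(1, pi, exp(1), sqrt(2), log(3)), length(models[[1L]]@Q))
  h <- vapply(models, function(m) sum(m@Q * w), numeric(1))
  key <- format(h, digits = 17)
  group <- integer(length(models))
  reps <- integer(0)
  repKey <- character(0)
  for (i in seq_along(models)) {
    found <- 0L
    for (cand in which(repKey == key[i])) {
      if (identical(models[[reps[cand]]]@Q, models[[i]]@Q)) {
        found <- cand
        break
      }
    }
    if (found == 0L) {
      reps <- c(reps, i)
      repKey <- c(repKey, key[i])
      found <- length(reps)
    }
    group[i] <- found
  }
  list(group = group, reps = reps)
}

# Per-site RateMatrix list for a profile.
.siteMatrices <- function(profile, codonFreqs = NULL) {
  if (is(profile, "SiteRateProfile")) {
    parts <- .mg94Parts(codonFreqs)
    return(lapply(seq_len(nSites(profile)), function(k)
      .mg94FromParts(profile@dN[k], profile@dS[k], parts)))
  }
  if (is(profile, "MutSelProfile")) {
    return(lapply(seq_len(nSites(profile)), function(k)
      hb98Matrix(profile@fitness[k, ], profile@mutation)))
  }
  stop("profile must be a SiteRateProfile or MutSelProfile")
}

#' Evolve a codon alignment along a tree
#'
#' Simulates one codon state per site per node: the root state is drawn
#' from each site's stationary distribution and each child state from the
#' transition kernel `exp(Q t)` of its edge, independently across sites.
#' Fully reproducible from the RNG state.
#'
#' @param tree ape `phylo` with branch lengths (>= 0).
#' @param siteModels list with one `RateMatrix` per site.
#' @return A `CodonAlignment` with one row per leaf.
#' @export
#' @examples
#' set.seed(7)
#' tr <- makeBalancedTree(4, 0.3)
#' q <- mg94Matrix(dN = 0.5)
#' aln <- evolveAlignment(tr, list(q, q, q))
#' nSites(aln)
evolveAlignment <- function(tree, siteModels) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0) ||
      any(!is.finite(tree$edge.length)))
    stop("tree must have finite nonnegative branch lengths")
  nS <- length(siteModels)
  if (nS == 0L) stop("need at least one site model")
  nTip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  edge <- tr$edge
  elen <- tr$edge.length
  nNode <- nTip + tr$Nnode

  # identical site models (common under repeated draws) share one
  # eigendecomposition and one set of sampling tables
  grp <- .groupModels(siteModels)
  nG <- length(grp$reps)
  factories <- lapply(grp$reps, function(k) .transitionFactory(siteModels[[k]]))
  pis <- lapply(grp$reps, function(k) siteModels[[k]]@stationary)
  nStates <- length(pis[[1L]])

  # row-stacked cumulative transition probabilities per unique edge length:
  # rows (model group g, state s) at offset (g-1)*nStates + s
  uniqLen <- unique(elen)
  cumByLen <- lapply(uniqLen, function(t) {
    big <- matrix(0, nStates * nG, nStates)
    for (g in seq_len(nG)) {
      P <- factories[[g]](t)
      big[((g - 1L) * nStates + 1L):(g * nStates), ] <-
        t(apply(P, 1L, cumsum))
    }
    if (any(!is.finite(big)))
      stop("non-finite transition probabilities at edge length ", t)
    big
  })
  names(cumByLen) <- format(uniqLen, digits = 15)

  states <- matrix(NA_integer_, nNode, nS)
  root <- nTip + 1L
  states[root, ] <- vapply(seq_len(nS), function(k)
    sample.int(nStates, 1L, prob = pis[[grp$group[k]]]), integer(1))
  offs <- (grp$group - 1L) * nStates
  for (e in seq_len(nrow(edge))) {
    cum <- cumByLen[[format(elen[e], digits = 15)]]
    rows <- offs + states[edge[e, 1L], ]
    C <- cum[rows, , drop = FALSE]
    u <- runif(nS)
    states[edge[e, 2L], ] <- max.col(1 * (C >= u), ties.method = "first")
  }
  codons <- matrix(.SENSE_CODONS[states[seq_len(nTip), , drop = FALSE]],
                   nTip, nS, dimnames = list(tr$tip.label, NULL))
  new("CodonAlignment", codons = codons)
}

#' Simulate an alignment from a rate profile
#'
#' Convenience wrapper: builds the per-site substitution matrices for
#' `profile` and evolves them along `tree`.
#'
#' @param tree ape `phylo` with branch lengths.
#' @param profile `SiteRateProfile` or `MutSelProfile`.
#' @param codonFreqs codon frequencies for dN/dS-model sites (default
#'   uniform); ignored for MutSel profiles.
#' @return A `CodonAlignment`.
#' @export
simulateAlignment <- function(tree, profile, codonFreqs = NULL) {
  evolveAlignment(tree, .siteMatrices(profile, codonFreqs))
}
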