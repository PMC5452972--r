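# S4 classes. Phylogenies are ape "phylo" objects throughout.

setOldClass("phylo")

#' CodonAlignment: a gapless alignment of sense codons
#'
#' Taxa-by-sites matrix of codon states (61 sense codons of the universal
#' code). No gaps and no stop codons are permitted.
#'
#' @slot codons character matrix, `nTaxa x nSites`, each entry a sense codon;
#'   rownames are the taxon labels.
#' @export
setClass("CodonAlignment", representation(codons = "matrix"))

setValidity("CodonAlignment", function(object) {
  m <- object@codons
  if (!is.character(m) || length(m) == 0L)
    return("codon matrix must be a nonempty character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("rownames (taxon labels) must be present and unique")
  bad <- !(m %in% .SENSE_CODONS)
  if (any(bad)) {
    u <- unique(m[bad])
    return(paste0("invalid codon state(s): ", paste(head(u, 5), collapse = ", "),
                  " (stop codons and gaps are not allowed)"))
  }
  TRUE
})

#' AminoAcidAlignment: an alignment of amino-acid residues
#'
#' Taxa-by-sites matrix of one-letter residue codes. The 20 standard residues
#' are the model states; `-` and `X` are accepted and treated as missing data
#' in likelihood computations.
#'
#' @slot residues character matrix, `nTaxa x nSites`; rownames are taxon
#'   labels.
#' @export
setClass("AminoAcidAlignment", representation(residues = "matrix"))

setValidity("AminoAcidAlignment", function(object) {
  m <- object@residues
  if (!is.character(m) || length(m) == 0L)
    return("residue matrix must be a nonempty character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("rownames (taxon labels) must be present and unique")
  ok <- m %in% c(.AA_ORDER, "-", "X")
  if (!all(ok))
    return(paste0("invalid residue state(s): ",
                  paste(head(unique(m[!ok]), 5), collapse = ", ")))
  TRUE
})

#' RateMatrix: an instantaneous substitution rate matrix
#'
#' A proper rate matrix (nonnegative off-diagonals, zero row sums) together
#' with its stationary distribution. Used for 61-state codon processes and
#' 20-state amino-acid processes alike.
#'
#' @slot Q numeric square matrix with dimnames giving the state labels.
#' @slot stationary numeric stationary distribution (sums to one).
#' @export
setClass("RateMatrix", representation(Q = "matrix", stationary = "numeric"))

setValidity("RateMatrix", function(object) {
  Q <- object@Q
  if (nrow(Q) != ncol(Q)) return("Q must be square")
  if (is.null(rownames(Q))) return("Q must carry state labels as dimnames")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) return("off-diagonal rates must be nonnegative")
  if (max(abs(rowSums(Q))) > 1e-8) return("rows of Q must sum to zero")
  p <- object@stationary
  if (length(p) != nrow(Q)) return("stationary length must match Q")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    return("stationary must be a probability vector")
  TRUE
})

#' SiteRateProfile: per-site (dN, dS) ground truth
#'
#' @slot dN nonnegative nonsynonymous rates, one per site.
#' @slot dS positive synonymous rates, one per site.
#' @export
setClass("SiteRateProfile", representation(dN = "numeric", dS = "numeric"))

setValidity("SiteRateProfile", function(object) {
  if (length(object@dN) != length(object@dS))
    return("dN and dS must have equal length")
  if (any(!is.finite(object@dN)) || any(object@dN < 0))
    return("dN must be finite and nonnegative")
  if (any(!is.finite(object@dS)) || any(object@dS <= 0))
    return("dS must be finite and strictly positive")
  TRUE
})

#' MutSelProfile: per-site codon fitness landscape
#'
#' Site-specific codon fitnesses (log scale, defined up to an additive
#' constant per site) for a Halpern-Bruno mutation-selection process,
#' together with the 4x4 nucleotide mutation rate matrix shared by all
#' sites. Scaled selection coefficients are `S_ij = f_j - f_i`.
#'
#' @slot fitness numeric matrix, `nSites x 61`, columns in
#'   \code{\link{senseCodons}} order.
#' @slot mutation numeric 4x4 nucleotide mutation rate matrix (rows sum to
#'   zero) with dimnames A, C, G, T.
#' @export
setClass("MutSelProfile",
         representation(fitness = "matrix", mutation = "matrix"))

setValidity("MutSelProfile", function(object) {
  f <- object@fitness
  if (ncol(f) != .NCODON) return("fitness must have 61 columns (sense codons)")
  if (any(!is.finite(f))) return("fitness values must be finite")
  m <- object@mutation
  if (!all(dim(m) == c(4L, 4L))) return("mutation must be 4x4")
  if (is.null(rownames(m)) || !identical(rownames(m), c("A", "C", "G", "T")))
    return("mutation matrix dimnames must be A, C, G, T")
  off <- m; diag(off) <- 0
  if (any(off < 0)) return("mutation off-diagonals must be nonnegative")
  if (max(abs(rowSums(m))) > 1e-8) return("mutation rows must sum to zero")
  TRUE
})

#' RateEstimates: per-site rate scores with a normalization state
#'
#' Container shared by codon-level dN/dS scores and amino-acid relative
#' rates. The `normalization` flag records whether scores are raw, divided
#' by their mean (`mean1`), or z-transformed (`zscore`).
#'
#' @slot scores numeric per-site scores.
#' @slot scoreKind `"dnds"` or `"aa_rate"`.
#' @slot normalization `"raw"`, `"mean1"`, or `"zscore"`.
#' @slot details list of method diagnostics (e.g. per-site log-likelihoods,
#'   invariant-site flags, fitted gamma shape).
#' @export
setClass("RateEstimates",
         representation(scores = "numeric", scoreKind = "character",
                        normalization = "character", details = "list"),
         prototype(details = list()))

setValidity("RateEstimates", function(object) {
  if (!object@scoreKind %in% c("dnds", "aa_rate"))
    return("scoreKind must be 'dnds' or 'aa_rate'")
  if (!object@normalization %in% c("raw", "mean1", "zscore"))
    return("normalization must be 'raw', 'mean1' or 'zscore'")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  if (object@normalization == "mean1" &&
      abs(mean(object@scores) - 1) > 1e-9)
    return("mean1 scores must average to 1 within 1e-9")
  TRUE
})

#' GridConfig: one cell-grid of simulation conditions
#'
#' Describes a full simulation design: the branch-length by taxon-count
#' grid, alignment length, replicate count, the rate-drawing regime, and a
#' master seed from which all per-replicate seeds are derived.
#'
#' @slot branchLengths positive branch lengths (divergence per edge).
#' @slot taxaCounts powers of two, the leaf counts of the balanced trees.
#' @slot nSites number of codon sites per alignment.
#' @slot nReplicates replicate alignments per grid cell.
#' @slot regime one of `constant_dS`, `variable_dS`, `gamma`,
#'   `mutsel_neutral_syn`, `mutsel_codon_bias`.
#' @slot gammaShape,gammaRate shape/rate of the gamma dN/dS distribution
#'   (used by the `gamma` regime only).
#' @slot masterSeed integer master seed.
#' @export
setClass("GridConfig",
         representation(branchLengths = "numeric", taxaCounts = "numeric",
                        nSites = "numeric", nReplicates = "numeric",
                        regime = "character", gammaShape = "numeric",
                        gammaRate = "numeric", masterSeed = "numeric"))

.REGIMES <- c("constant_dS", "variable_dS", "gamma",
              "mutsel_neutral_syn", "mutsel_codon_bias")

setValidity("GridConfig", function(object) {
  if (length(object@branchLengths) == 0L || any(object@branchLengths <= 0))
    return("branchLengths must be nonempty and positive")
  n <- object@taxaCounts
  if (length(n) == 0L || any(n < 2) || any(n != as.integer(n)) ||
      any(bitwAnd(as.integer(n), as.integer(n) - 1L) != 0L))
    return("taxaCounts must be powers of two (>= 2)")
  if (object@nSites < 1) return("nSites must be >= 1")
  if (object@nReplicates < 1) return("nReplicates must be >= 1")
  if (!object@regime %in% .REGIMES)
    return(paste("regime must be one of:", paste(.REGIMES, collapse = ", ")))
  if (object@regime == "gamma" &&
      (object@gammaShape <= 0 || object@gammaRate <= 0))
    return("gammaShape and gammaRate must be positive for the gamma regime")
  TRUE
})

#' AARateModel: amino-acid replacement model with gamma rate categories
#'
#' An empirical reversible replacement process (exchangeabilities and
#' equilibrium frequencies) plus the discretized-gamma rate prior used for
#' empirical-Bayes site-rate inference.
#'
#' @slot name matrix name (`"JTT"`, `"LG"`, or `"WAG"`).
#' @slot exchangeability symmetric 20x20 exchangeability matrix.
#' @slot freqs equilibrium residue frequencies (length 20).
#' @slot nCat number of equal-probability gamma categories (>= 4).
#' @slot shape gamma shape; `NA_real_` means "estimate by maximum
#'   likelihood on the whole alignment" (empirical Bayes).
#' @export
setClass("AARateModel",
         representation(name = "character", exchangeability = "matrix",
                        freqs = "numeric", nCat = "numeric",
                        shape = "numeric"))

setValidity("AARateModel", function(object) {
  if (!all(dim(object@exchangeability) == c(20L, 20L)))
    return("exchangeability must be 20x20")
  if (max(abs(object@exchangeability - t(object@exchangeability))) > 1e-8)
    return("exchangeability must be symmetric")
  if (length(object@freqs) != 20L || abs(sum(object@freqs) - 1) > 1e-6)
    return("freqs must be 20 probabilities summing to 1")
  if (object@nCat < 4) return("nCat must be >= 4")
  if (!is.na(object@shape) && object@shape <= 0)
    return("shape must be positive (or NA to estimate)")
  TRUE
})
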