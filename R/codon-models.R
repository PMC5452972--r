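# Substitution-process construction: site-specific Muse-Gaut (dN/dS) codon
# matrices, Halpern-Bruno (HB98) mutation-selection matrices, and the
# expected dN/dS implied by scaled selection coefficients.
#
# Scaling convention: codon matrices are multiplied by one constant per
# model family (shared by all sites of an alignment) chosen so that a
# NEUTRAL site experiences one expected substitution per codon site per
# unit branch length. Branch lengths therefore read as neutral divergence,
# and relative rates across sites (the quantity of interest) are preserved
# exactly; a per-site mean-rate-1 rescaling would erase them.

#' Construct a site rate profile
#'
#' @param dN nonsynonymous rates (one per site).
#' @param dS synonymous rates, recycled to the length of `dN`.
#' @return A `SiteRateProfile`.
#' @export
#' @examples
#' siteRateProfile(dN = c(0.2, 1.1), dS = 1)
siteRateProfile <- function(dN, dS = 1) {
  new("SiteRateProfile", dN = as.numeric(dN),
      dS = rep_len(as.numeric(dS), length(dN)))
}

#' Construct a mutation-selection site profile
#'
#' @param fitness numeric matrix `nSites x 61` of codon fitnesses (log
#'   scale), columns in \code{\link{senseCodons}} order, or a length-61
#'   vector for a single site.
#' @param mutation 4x4 nucleotide mutation rate matrix, e.g. from
#'   \code{\link{mutationMatrix}}.
#' @return A `MutSelProfile`.
#' @export
mutSelProfile <- function(fitness, mutation = mutationMatrix()) {
  if (!is.matrix(fitness)) fitness <- matrix(fitness, nrow = 1L)
  colnames(fitness) <- .SENSE_CODONS
  new("MutSelProfile", fitness = fitness, mutation = mutation)
}

#' HKY-style nucleotide mutation rate matrix
#'
#' Reversible nucleotide mutation process with target-frequency rates
#' `mu[a, b] = kappa_ab * freq[b]` where `kappa_ab` equals `kappa` for
#' transitions (A<->G, C<->T) and 1 for transversions.
#'
#' @param nucFreqs equilibrium nucleotide frequencies, named A, C, G, T.
#' @param kappa transition/transversion rate ratio (default 1: no
#'   asymmetry).
#' @return 4x4 numeric matrix with zero row sums.
#' @export
#' @examples
#' mutationMatrix(c(A = 0.32, C = 0.18, G = 0.18, T = 0.32))
mutationMatrix <- function(nucFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           kappa = 1) {
  nuc <- c("A", "C", "G", "T")
  if (is.null(names(nucFreqs))) names(nucFreqs) <- nuc
  nucFreqs <- nucFreqs[nuc]
  if (anyNA(nucFreqs) || any(nucFreqs <= 0) || abs(sum(nucFreqs) - 1) > 1e-8)
    stop("nucFreqs must be positive A,C,G,T frequencies summing to 1")
  m <- outer(rep(1, 4), nucFreqs)
  dimnames(m) <- list(nuc, nuc)
  m["A", "G"] <- m["A", "G"] * kappa; m["G", "A"] <- m["G", "A"] * kappa
  m["C", "T"] <- m["C", "T"] * kappa; m["T", "C"] <- m["T", "C"] * kappa
  diag(m) <- 0
  diag(m) <- -rowSums(m)
  m
}

# Shared pieces of the MG94-style model for a given codon frequency
# vector: syn/nonsyn target-factor matrices and the neutral scale constant.
.mg94Parts <- function(codonFreqs = NULL) {
  if (is.null(codonFreqs)) codonFreqs <- rep(1 / .NCODON, .NCODON)
  if (length(codonFreqs) != .NCODON || any(codonFreqs <= 0) ||
      abs(sum(codonFreqs) - 1) > 1e-8)
    stop("codonFreqs must be 61 positive probabilities summing to 1")
  target <- matrix(codonFreqs, .NCODON, .NCODON, byrow = TRUE)
  syn <- ifelse(.codonTables$syn, target, 0)
  nonsyn <- ifelse(.codonTables$nonsyn, target, 0)
  neutral <- syn + nonsyn
  meanRate <- sum(codonFreqs * rowSums(neutral))
  list(freqs = codonFreqs, syn = syn, nonsyn = nonsyn,
       scale = 1 / meanRate)
}

#' Site-specific Muse-Gaut (MG94-style) codon rate matrix
#'
#' Single-nucleotide codon changes occur at rate `dS * pi_target`
#' (synonymous) or `dN * pi_target` (nonsynonymous), where `pi_target` is
#' the equilibrium frequency of the target codon; multi-nucleotide changes
#' have rate zero. The matrix is scaled so a neutral site (`dN = dS = 1`)
#' evolves at one expected substitution per unit branch length under the
#' same frequencies.
#'
#' @param dN nonsynonymous rate (>= 0) for this site.
#' @param dS synonymous rate (> 0), default 1.
#' @param codonFreqs equilibrium codon frequencies over the 61 sense
#'   codons; default uniform.
#' @return A `RateMatrix` (61 states).
#' @export
#' @examples
#' q <- mg94Matrix(dN = 0.5)
#' max(abs(rowSums(rateMatrix(q))))  # ~0
mg94Matrix <- function(dN, dS = 1, codonFreqs = NULL) {
  if (!is.finite(dN) || dN < 0) stop("dN must be finite and >= 0")
  if (!is.finite(dS) || dS <= 0) stop("dS must be finite and > 0")
  parts <- .mg94Parts(codonFreqs)
  .mg94FromParts(dN, dS, parts)
}

.mg94FromParts <- function(dN, dS, parts) {
  Q <- parts$scale * (dS * parts$syn + dN * parts$nonsyn)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(.SENSE_CODONS, .SENSE_CODONS)
  new("RateMatrix", Q = Q, stationary = parts$freqs)
}

# Fixation factor S / (1 - exp(-S)) with its removable singularity at 0.
.fixationFactor <- function(S) {
  g <- S / (1 - exp(-S))
  small <- abs(S) < 1e-8
  if (any(small)) g[small] <- 1
  g
}

# Codon-lifted neutral mutation process and its stationary distribution.
# mutation must be reversible (true for mutationMatrix()); the stationary
# weights are products of nucleotide stationary frequencies restricted to
# sense codons.
.liftedMutation <- function(mutation) {
  nuc <- c("A", "C", "G", "T")
  src <- t(.codonTables$targetNuc)        # src[i, j]: source nucleotide
  tgt <- .codonTables$targetNuc
  idx <- which(.codonTables$neighbor)
  M <- matrix(0, .NCODON, .NCODON, dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  M[idx] <- mutation[cbind(match(src[idx], nuc), match(tgt[idx], nuc))]
  piNt <- .nucStationary(mutation)
  cn <- .codonTables$codonNuc
  m <- piNt[cn[, 1]] * piNt[cn[, 2]] * piNt[cn[, 3]]
  m <- m / sum(m)
  # detailed-balance check of the restricted chain
  db <- max(abs(m * M - t(m * M)))
  if (db > 1e-10 * max(M))
    stop("mutation matrix is not reversible; HB98 construction requires a ",
         "reversible nucleotide mutation process")
  list(M = M, m = setNames(m, .SENSE_CODONS))
}

.nucStationary <- function(mutation) {
  e <- eigen(t(mutation))
  k <- which.min(abs(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("mutation matrix has no valid stationary vector")
  setNames(pmax(v, 0) / sum(pmax(v, 0)), c("A", "C", "G", "T"))
}

#' Halpern-Bruno (HB98) mutation-selection codon rate matrix
#'
#' For single-nucleotide neighbor codons i -> j, the substitution rate is
#' the mutation rate times the relative fixation probability
#' `S_ij / (1 - exp(-S_ij))`, with `S_ij = f_j - f_i` the scaled selection
#' coefficient (the factor is 1 at `S = 0`, its limit). The stationary
#' distribution is proportional to the mutation-stationary codon weights
#' times `exp(f)`, and detailed balance holds for reversible mutation. The
#' matrix is scaled so the neutral (all-equal-fitness) process evolves at
#' one expected substitution per unit branch length.
#'
#' @param fitness length-61 codon fitness vector (log scale; adding a
#'   constant changes nothing), in \code{\link{senseCodons}} order.
#' @param mutation 4x4 reversible nucleotide mutation matrix.
#' @return A `RateMatrix` (61 states).
#' @export
#' @examples
#' q <- hb98Matrix(rep(0, 61))          # neutral: reduces to mutation process
#' stationary(q)[1]
hb98Matrix <- function(fitness, mutation = mutationMatrix()) {
  if (length(fitness) != .NCODON || any(!is.finite(fitness)))
    stop("fitness must be 61 finite values")
  lift <- .liftedMutation(mutation)
  f <- fitness - max(fitness)
  S <- matrix(f, .NCODON, .NCODON, byrow = TRUE) - f
  Q <- lift$M * .fixationFactor(S)
  scale <- 1 / sum(lift$m * rowSums(lift$M))
  Q <- Q * scale
  diag(Q) <- -rowSums(Q)
  pi <- lift$m * exp(f)
  pi <- pi / sum(pi)
  new("RateMatrix", Q = Q, stationary = unname(pi))
}

#' Expected dN/dS from scaled selection coefficients
#'
#' The stationary nonsynonymous substitution flux of the HB98 process,
#' divided by the corresponding flux under neutrality (all fixation factors
#' 1, mutation-stationary codon distribution). Equals 1 exactly for a
#' neutral fitness profile and is invariant to adding a constant to all
#' fitnesses.
#'
#' @param fitness length-61 codon fitness vector.
#' @param mutation 4x4 reversible nucleotide mutation matrix.
#' @return Nonnegative number.
#' @export
#' @examples
#' expectedDnDs(rep(0, 61))  # 1
expectedDnDs <- function(fitness, mutation = mutationMatrix()) {
  if (length(fitness) != .NCODON || any(!is.finite(fitness)))
    stop("fitness must be 61 finite values")
  lift <- .liftedMutation(mutation)
  f <- fitness - max(fitness)
  S <- matrix(f, .NCODON, .NCODON, byrow = TRUE) - f
  Qn <- lift$M * .fixationFactor(S)   # unscaled; the constant cancels
  pi <- lift$m * exp(f)
  pi <- pi / sum(pi)
  ns <- .codonTables$nonsyn
  num <- sum((pi * Qn)[ns])
  den <- sum((lift$m * lift$M)[ns])
  num / den
}

#' Stationary distribution of a rate matrix
#'
#' Solves `v Q = 0` with `v >= 0`, `sum(v) = 1` by eigen-decomposition of
#' the transpose, and verifies the residual.
#'
#' @param Q a `RateMatrix` or plain numeric rate matrix (zero row sums).
#' @return Probability vector with residual `max |vQ| <= 1e-10` (relative
#'   to the magnitude of Q).
#' @export
stationaryDistribution <- function(Q) {
  if (is(Q, "RateMatrix")) Q <- Q@Q
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  e <- eigen(t(Q))
  mag <- max(abs(Q))
  nearZero <- which(abs(e$values) < 1e-8 * max(mag, 1))
  if (length(nearZero) > 1L)
    stop("rate matrix appears reducible: ", length(nearZero),
         " near-zero eigenvalues")
  k <- which.min(abs(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  if (any(v < -1e-8))
    stop("no valid stationary distribution (matrix reducible or not a ",
         "proper rate matrix)")
  v <- pmax(v, 0)
  v <- v / sum(v)
  resid <- max(abs(v %*% Q))
  if (resid > 1e-10 * max(mag, 1))
    stop("stationary solve failed: residual ", signif(resid, 3))
  setNames(v, rownames(Q))
}
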