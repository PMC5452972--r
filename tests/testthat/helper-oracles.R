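# Independent oracles, deliberately implemented apart from the package's
# code paths: dense matrix exponentials via Matrix::expm, explicit
# ancestral-state enumeration for small trees, and brute-force flux sums.

# Transition matrix by Pade approximation (independent of the package's
# spectral route).
oracleProbMatrix <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

# Column log-likelihood on a rooted binary tree with <= 3 tips by explicit
# summation over all internal-node state assignments.
# tips: integer state indices in tip order; Q: rate matrix; pi: root freqs.
# For 2 tips: root -> (tip1, tip2) with edge lengths b. For 3 tips
# (caterpillar): root -> tip3 and root -> inner; inner -> (tip1, tip2).
oracleLogLik2 <- function(tips, Q, pi, b1, b2) {
  P1 <- oracleProbMatrix(Q, b1)
  P2 <- oracleProbMatrix(Q, b2)
  n <- nrow(Q)
  tot <- 0
  for (r in seq_len(n)) {
    tot <- tot + pi[r] * P1[r, tips[1]] * P2[r, tips[2]]
  }
  log(tot)
}

oracleLogLik3 <- function(tips, Q, pi, bRootTip3, bRootInner, bInner1,
                          bInner2) {
  Pt3 <- oracleProbMatrix(Q, bRootTip3)
  Pin <- oracleProbMatrix(Q, bRootInner)
  P1 <- oracleProbMatrix(Q, bInner1)
  P2 <- oracleProbMatrix(Q, bInner2)
  n <- nrow(Q)
  tot <- 0
  for (r in seq_len(n)) {
    for (a in seq_len(n)) {
      tot <- tot + pi[r] * Pt3[r, tips[3]] * Pin[r, a] *
        P1[a, tips[1]] * P2[a, tips[2]]
    }
  }
  log(tot)
}

# Brute-force expected dN/dS: double sum over all 61 x 61 codon pairs with
# explicit fixation factors, written without the package's lifted-mutation
# helper.
oracleExpectedDnDs <- function(fitness, mutation) {
  codons <- senseCodons()
  nuc <- c("A", "C", "G", "T")
  piNt <- Re(eigen(t(mutation))$vectors[, which.min(abs(eigen(t(mutation))$values))])
  piNt <- setNames(piNt / sum(piNt), nuc)
  cmat <- do.call(rbind, strsplit(codons, ""))
  m <- apply(cmat, 1, function(x) prod(piNt[x]))
  m <- m / sum(m)
  pi <- m * exp(fitness - max(fitness))
  pi <- pi / sum(pi)
  aa <- translateCodons(codons)
  num <- 0; den <- 0
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i == j) next
      diff <- which(cmat[i, ] != cmat[j, ])
      if (length(diff) != 1L) next
      if (aa[i] == aa[j]) next
      mu <- mutation[cmat[i, diff], cmat[j, diff]]
      S <- fitness[j] - fitness[i]
      g <- if (abs(S) < 1e-8) 1 else S / (1 - exp(-S))
      num <- num + pi[i] * mu * g
      den <- den + m[i] * mu
    }
  }
  as.numeric(num / den)
}

# Spearman correlation by the explicit rank formula (average ranks,
# product-moment on ranks).
oracleSpearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Posterior-mean site rate over fixed gamma categories, by direct
# per-category enumeration likelihoods on a 3-taxon caterpillar tree.
oraclePosteriorMeanRate <- function(tips, Qaa, freqs, b, rates) {
  lik <- vapply(rates, function(r) {
    exp(oracleLogLik3(tips, Qaa * r, freqs, b, b, b, b))
  }, numeric(1))
  sum(rates * lik) / sum(lik)
}

# Small deterministic codon alignment fixture.
toyCodonAlignment <- function() {
  codonAlignment(rbind(
    t1 = c("ATG", "AAA", "CTT", "GGA"),
    t2 = c("ATG", "AAG", "CTC", "GGA"),
    t3 = c("ATG", "AAA", "CTT", "GGC"),
    t4 = c("ATG", "AGA", "CTG", "GGA")))
}
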