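test_that("MG94 matrix obeys its defining structure", {
  # dN = dS = 1 with uniform frequencies: all single-nucleotide-neighbor
  # rates equal; stationary uniform over the 61 sense codons
  q1 <- mg94Matrix(dN = 1, dS = 1)
  Q <- rateMatrix(q1)
  off <- Q[upper.tri(Q) | lower.tri(Q)]
  pos <- off[off > 0]
  expect_true(max(pos) - min(pos) < 1e-12)
  expect_equal(stationary(q1), rep(1 / 61, 61))
  # dN = 0: every nonsynonymous entry exactly 0
  q0 <- mg94Matrix(dN = 0, dS = 1)
  codons <- senseCodons()
  i <- which(codons == "TTT"); j <- which(codons == "TCT")  # F -> S
  expect_identical(rateMatrix(q0)[i, j], 0)
  # two-nucleotide changes always 0
  i <- which(codons == "AAA"); j <- which(codons == "ACC")
  expect_identical(rateMatrix(mg94Matrix(1.3))[i, j], 0)
  # row sums zero
  expect_lt(max(abs(rowSums(Q))), 1e-12)
})

test_that("HB98 reduces to the mutation process for equal fitnesses", {
  mut <- mutationMatrix(c(A = 0.32, C = 0.18, G = 0.18, T = 0.32))
  q <- hb98Matrix(rep(3, 61), mut)
  # fixation factor 1 everywhere: matrix equals the scaled codon-lifted
  # mutation process; expected dN/dS is exactly 1
  expect_equal(expectedDnDs(rep(3, 61), mut), 1, tolerance = 1e-10)
  # stationary matches the mutation-stationary codon weights
  pi <- stationary(q)
  expect_equal(as.numeric(pi %*% rateMatrix(q)), rep(0, 61),
               tolerance = 1e-12)
})

test_that("HB98 satisfies detailed balance for reversible mutation", {
  set.seed(42)
  mut <- mutationMatrix(c(A = 0.3, C = 0.25, G = 0.15, T = 0.3), kappa = 2)
  for (i in 1:5) {
    f <- rnorm(61, sd = 1.5)
    q <- hb98Matrix(f, mut)
    pi <- stationary(q)
    flux <- pi * rateMatrix(q)
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    expect_lt(max(abs(rowSums(rateMatrix(q)))), 1e-12)
  }
})

test_that("fixation factor handles the S -> 0 limit without blowup", {
  f <- rep(0, 61)
  f[2] <- 1e-12
  q <- hb98Matrix(f)
  expect_true(all(is.finite(rateMatrix(q))))
  qn <- hb98Matrix(rep(0, 61))
  expect_equal(rateMatrix(q), rateMatrix(qn), tolerance = 1e-9)
})

test_that("expected dN/dS matches the brute-force flux oracle", {
  mut <- mutationMatrix()
  # two amino-acid fitness classes at +-0.5 (S = +-1 between classes)
  codons <- senseCodons()
  aa <- translateCodons(codons)
  classA <- aa %in% c("A", "G", "P", "S", "T", "V", "L", "I", "F", "M")
  f <- ifelse(classA, 0.5, -0.5)
  expect_equal(expectedDnDs(f, mut), oracleExpectedDnDs(f, mut),
               tolerance = 1e-10)
  # and under unequal nucleotide frequencies with random fitnesses
  mut2 <- mutationMatrix(c(A = 0.32, C = 0.18, G = 0.18, T = 0.32))
  set.seed(9)
  f2 <- rnorm(61)
  expect_equal(expectedDnDs(f2, mut2), oracleExpectedDnDs(f2, mut2),
               tolerance = 1e-10)
})

test_that("expected dN/dS behaves at its limits and symmetries", {
  # strong purifying selection: one amino acid far above all others
  codons <- senseCodons()
  f <- ifelse(translateCodons(codons) == "L", 20, 0)
  expect_lt(expectedDnDs(f), 0.01)
  # invariance to additive constants
  set.seed(4)
  g <- rnorm(61)
  expect_equal(expectedDnDs(g), expectedDnDs(g + 7.3), tolerance = 1e-10)
})

test_that("the two model families agree where they overlap", {
  # MG94 with ratio omega and uniform frequencies: stationary
  # nonsynonymous flux over its neutral counterpart equals omega
  omega <- 0.37
  q <- mg94Matrix(dN = omega, dS = 1)
  qn <- mg94Matrix(dN = 1, dS = 1)
  codons <- senseCodons()
  aa <- translateCodons(codons)
  nonsyn <- outer(aa, aa, "!=") &
    (rateMatrix(qn) > 0 | t(rateMatrix(qn)) > 0)
  pi <- stationary(q)
  num <- sum((pi * rateMatrix(q))[nonsyn])
  den <- sum((stationary(qn) * rateMatrix(qn))[nonsyn])
  expect_equal(num / den, omega, tolerance = 1e-10)
})

test_that("stationaryDistribution solves vQ = 0 to tolerance", {
  q <- mg94Matrix(1, 1)
  v <- stationaryDistribution(q)
  expect_equal(as.numeric(v), rep(1 / 61, 61), tolerance = 1e-10)
  # HB98: matches the construction's stationary vector
  set.seed(12)
  f <- rnorm(61)
  qh <- hb98Matrix(f)
  expect_equal(unname(stationaryDistribution(qh)),
               unname(stationary(qh)), tolerance = 1e-8)
  resid <- max(abs(stationaryDistribution(qh) %*% rateMatrix(qh)))
  expect_lt(resid, 1e-10)
  # cross-check against the long-time matrix exponential limit
  Plong <- oracleProbMatrix(rateMatrix(qh), 2000)
  expect_equal(unname(Plong[1, ]), unname(stationary(qh)),
               tolerance = 1e-6)
})

test_that("degenerate rate matrices are rejected", {
  Q <- diag(0, 4)  # all-zero: every state absorbing, reducible
  dimnames(Q) <- list(letters[1:4], letters[1:4])
  expect_error(stationaryDistribution(Q), "reducible")
  expect_error(mg94Matrix(-1), "dN")
  expect_error(mg94Matrix(1, 0), "dS")
  expect_error(mg94Matrix(1, 1, rep(1, 61)), "codonFreqs")
  expect_error(hb98Matrix(c(NA, rep(0, 60))), "finite")
})

test_that("codon predicates implement the universal code", {
  expect_equal(length(senseCodons()), 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% senseCodons()))
  expect_true(isCodonNeighbor("AAA", "AAG"))
  expect_false(isCodonNeighbor("AAA", "ACC"))
  expect_true(isSynonymousPair("AAA", "AAG"))    # K/K
  expect_false(isSynonymousPair("AAA", "AGA"))   # K/R
  expect_identical(translateCodons(c("ATG", "TGG")), c("M", "W"))
  expect_error(translateCodons("TAA"), "sense")
})
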