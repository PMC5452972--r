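test_that("translation is positionwise and shape-preserving", {
  aln <- codonAlignment(rbind(a = c("ATG", "CTT"), b = c("ATG", "CTC")))
  aa <- translateAlignment(aln)
  expect_identical(stateMatrix(aa)[, 1], c(a = "M", b = "M"))
  expect_identical(stateMatrix(aa)[, 2], c(a = "L", b = "L"))
  set.seed(19)
  big <- simulateAlignment(makeBalancedTree(4, 0.2),
                           drawProfiles("constant_dS", 100))
  expect_equal(dim(stateMatrix(translateAlignment(big))),
               dim(stateMatrix(big)))
})

test_that("replacement model tables are valid reversible processes", {
  for (name in c("JTT", "LG", "WAG")) {
    mod <- aaRateModel(name)
    expect_equal(sum(mod@freqs), 1, tolerance = 1e-6)
    Q <- siteRates:::.aaQ(mod)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # detailed balance and mean rate 1
    flux <- mod@freqs * Q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    expect_equal(-sum(mod@freqs * diag(Q)), 1, tolerance = 1e-12)
  }
})

test_that("gamma category rates are mean-1 equal-probability midpoints", {
  for (a in c(0.3, 1, 5)) {
    r <- siteRates:::.gammaCategoryRates(a, 16)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
    expect_length(r, 16)
  }
})

test_that("identical columns receive identical scores", {
  m <- matrix(rep(c("M", "L", "M", "M"), 6), nrow = 4,
              dimnames = list(paste0("t", 1:4), NULL))
  aln <- aminoAcidAlignment(m)
  tr <- makeBalancedTree(4, 0.3)
  est <- aaRates(aln, tr, aaRateModel(nCat = 8, shape = 1))
  expect_true(max(scores(est)) - min(scores(est)) < 1e-12)
  expect_true(all(scores(est) > 0))
})

test_that("more variable columns on the same tree score higher", {
  tr <- makeBalancedTree(4, 0.3)
  m <- cbind(c("M", "M", "M", "M"),   # conserved
             c("M", "M", "M", "L"),   # one change
             c("M", "L", "K", "F"))   # saturated
  rownames(m) <- paste0("t", 1:4)
  est <- aaRates(aminoAcidAlignment(m), tr, aaRateModel(nCat = 8, shape = 1))
  expect_true(all(diff(scores(est)) > 0))
})

test_that("posterior mean rates match the per-category oracle, 3 taxa", {
  txt <- "((t1:0.2,t2:0.2):0.2,t3:0.2);"
  tr <- ape::read.tree(text = txt)
  mod <- aaRateModel("JTT", nCat = 4, shape = 0.7)
  Qaa <- siteRates:::.aaQ(mod)
  rates <- siteRates:::.gammaCategoryRates(0.7, 4)
  cols <- list(c("M", "M", "M"), c("M", "L", "M"), c("A", "R", "W"))
  m <- do.call(cbind, cols)
  rownames(m) <- c("t1", "t2", "t3")
  est <- aaRates(aminoAcidAlignment(m), tr, mod)
  aaOrd <- rownames(Qaa)
  for (k in seq_along(cols)) {
    oracle <- oraclePosteriorMeanRate(match(cols[[k]], aaOrd), Qaa,
                                      mod@freqs, 0.2, rates)
    expect_equal(scores(est)[k], oracle, tolerance = 1e-8)
  }
})

test_that("likelihoods are invariant to the rate-time rescaling", {
  # the site likelihood depends on rate and branch length only through
  # their product r * t: multiplying all edge lengths by c and dividing
  # the rate by c changes nothing (the identifiability that the mean-1
  # score normalization resolves)
  set.seed(29)
  tr <- makeBalancedTree(8, 0.25)
  aln <- translateAlignment(simulateAlignment(tr, drawProfiles("constant_dS", 10)))
  mod <- aaRateModel(nCat = 8)
  Q <- siteRates:::.aaQ(mod)
  fac <- siteRates:::.transitionFactory(Q, mod@freqs)
  idx <- siteRates:::.encodeStates(stateMatrix(aln)[tr$tip.label, ],
                                   siteRates:::.AA_ORDER)
  c0 <- 3.7
  tr2 <- tr; tr2$edge.length <- tr$edge.length * c0
  for (r in c(0.2, 1, 4)) {
    ll1 <- siteRates:::.pruneLogLik(idx, tr, function(t) fac(r * t),
                                    mod@freqs, 20L)
    ll2 <- siteRates:::.pruneLogLik(idx, tr2, function(t) fac((r / c0) * t),
                                    mod@freqs, 20L)
    expect_equal(ll1, ll2, tolerance = 1e-10)
  }
})

test_that("score normalization follows its contracts", {
  est <- new("RateEstimates", scores = c(1, 2, 3), scoreKind = "aa_rate",
             normalization = "raw")
  m1 <- normalizeScores(est, "mean1")
  expect_equal(scores(m1), c(0.5, 1.0, 1.5))
  expect_equal(mean(scores(m1)), 1, tolerance = 1e-12)
  expect_identical(normalization(m1), "mean1")
  # idempotent
  expect_equal(scores(normalizeScores(m1, "mean1")), scores(m1))
  z <- normalizeScores(est, "zscore")
  expect_equal(mean(scores(z)), 0, tolerance = 1e-12)
  expect_equal(sd(scores(z)), 1, tolerance = 1e-12)
  flat <- new("RateEstimates", scores = rep(2, 4), scoreKind = "aa_rate",
              normalization = "raw")
  expect_error(normalizeScores(flat, "zscore"), "deviation")
  zero <- new("RateEstimates", scores = rep(0, 4), scoreKind = "dnds",
              normalization = "raw")
  expect_error(normalizeScores(zero, "mean1"), "mean")
})

test_that("gaps are treated as missing observations", {
  m <- rbind(t1 = c("M", "L"), t2 = c("M", "-"), t3 = c("M", "L"),
             t4 = c("M", "X"))
  tr <- makeBalancedTree(4, 0.3)
  est <- aaRates(aminoAcidAlignment(m), tr, aaRateModel(nCat = 4, shape = 1))
  expect_true(all(is.finite(scores(est)) & scores(est) > 0))
})
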