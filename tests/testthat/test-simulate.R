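test_that("profile draws respect each regime's distributional contract", {
  set.seed(31)
  p1 <- drawProfiles("constant_dS", 200)
  expect_true(all(dS(p1) == 1))
  expect_true(all(dN(p1) >= 0.1 & dN(p1) <= 1.6))

  p2 <- drawProfiles("variable_dS", 200)
  expect_true(all(dS(p2) >= 0.5 & dS(p2) <= 2))
  expect_true(all(dNdS(p2) >= 0.1 - 1e-12 & dNdS(p2) <= 1.6 + 1e-12))
  expect_equal(dN(p2), dS(p2) * dNdS(p2), tolerance = 1e-15)

  expect_error(drawProfiles("nonsense", 10), "unknown regime")
})

test_that("gamma-regime draws have the analytic gamma mean", {
  # Gamma(shape a, rate b) has mean a/b; check the integrase setting at
  # large n within 3 standard errors (se = sqrt(a)/b/sqrt(n))
  set.seed(99)
  n <- 1e5
  p <- drawProfiles("gamma", n, params = list(gammaShape = 0.312,
                                              gammaRate = 1.027))
  m <- mean(dNdS(p))
  se <- sqrt(0.312) / 1.027 / sqrt(n)
  expect_lt(abs(m - 0.312 / 1.027), 3 * se)
  expect_true(all(dS(p) == 1))
})

test_that("mutsel profile draws produce valid fitness landscapes", {
  set.seed(17)
  p <- drawProfiles("mutsel_neutral_syn", 12)
  expect_s4_class(p, "MutSelProfile")
  expect_equal(nSites(p), 12)
  # neutral synonymous codons: synonymous fitnesses equal within a site
  codons <- senseCodons()
  aa <- translateCodons(codons)
  lysine <- which(aa == "K")
  expect_equal(unname(p@fitness[1, lysine[1]]),
               unname(p@fitness[1, lysine[2]]))
  # codon bias regime breaks that equality
  pb <- drawProfiles("mutsel_codon_bias", 3)
  expect_false(isTRUE(all.equal(pb@fitness[1, lysine[1]],
                                pb@fitness[1, lysine[2]])))
  # expected dN/dS is finite and spread out across sites
  ed <- trueDnDs(p)
  expect_true(all(is.finite(ed) & ed >= 0))
  expect_gt(sd(ed), 0.01)
})

test_that("evolution along a zero-length tree copies the root state", {
  tr <- makeBalancedTree(8, 1)  # lengths overwritten below
  tr$edge.length[] <- 0
  q <- mg94Matrix(0.8)
  set.seed(5)
  aln <- evolveAlignment(tr, rep(list(q), 5))
  m <- stateMatrix(aln)
  for (k in 1:5) expect_equal(length(unique(m[, k])), 1L)
})

test_that("simulated alignments have one column per site profile", {
  set.seed(6)
  tr <- makeBalancedTree(16, 0.2)
  aln <- simulateAlignment(tr, drawProfiles("constant_dS", 100))
  expect_equal(nSites(aln), 100)
  expect_equal(nTaxa(aln), 16)
  expect_setequal(taxonNames(aln), tr$tip.label)
})

test_that("cherry joint pattern frequencies match pi exp(Q 2b)", {
  # two tips at distance 2b; the joint distribution of (tip1, tip2)
  # patterns is pi_i [exp(Q 2b)]_ij; simulate many iid sites of one model
  b <- 0.3
  tr <- makeBalancedTree(2, b)
  q <- mg94Matrix(dN = 0.9, dS = 1)
  nRep <- 20000
  set.seed(8)
  aln <- evolveAlignment(tr, rep(list(q), nRep))
  m <- stateMatrix(aln)
  codons <- senseCodons()
  i <- match(m["t1", ], codons)
  j <- match(m["t2", ], codons)
  emp <- table(factor(i, levels = 1:61), factor(j, levels = 1:61)) / nRep
  P2b <- oracleProbMatrix(rateMatrix(q), 2 * b)
  expected <- stationary(q) * P2b
  # standardized deviations for cells with non-negligible expectation,
  # and an aggregate goodness-of-fit statistic within chi-square range
  big <- expected > 5 / nRep
  z <- (emp[big] - expected[big]) / sqrt(expected[big] / nRep)
  expect_lt(max(abs(z)), 5)
  k <- sum(big)
  expect_lt(sum(z^2), k + 5 * sqrt(2 * k))
})

test_that("simulation is reproducible from the seed", {
  tr <- makeBalancedTree(8, 0.15)
  prof <- local({ set.seed(3); drawProfiles("constant_dS", 20) })
  mats <- lapply(seq_len(20), function(k)
    mg94Matrix(dN(prof)[k], dS(prof)[k]))
  set.seed(44)
  a1 <- evolveAlignment(tr, mats)
  set.seed(44)
  a2 <- evolveAlignment(tr, mats)
  expect_identical(stateMatrix(a1), stateMatrix(a2))
  # and a different seed gives different data
  set.seed(45)
  a3 <- evolveAlignment(tr, mats)
  expect_false(identical(stateMatrix(a3), stateMatrix(a1)))
})

test_that("each column's distribution depends only on its own profile", {
  # per-site independence: reversing the order of two very different site
  # models swaps the columns' behavior (checked on summary statistics
  # over replicate simulations with matched seeds)
  tr <- makeBalancedTree(32, 0.4)
  qSlow <- mg94Matrix(0.05)
  qFast <- mg94Matrix(1.6)
  nVar <- function(aln, k)
    length(unique(translateCodons(stateMatrix(aln)[, k])))
  set.seed(70)
  a <- evolveAlignment(tr, list(qSlow, qFast))
  set.seed(70)
  b <- evolveAlignment(tr, list(qFast, qSlow))
  # fast sites show more residue variability than slow sites, in either
  # position
  expect_gte(nVar(a, 2), nVar(a, 1))
  expect_gte(nVar(b, 1), nVar(b, 2))
})

test_that("observed amino-acid variability tracks true dN on average", {
  set.seed(23)
  tr <- makeBalancedTree(128, 0.3)
  prof <- drawProfiles("constant_dS", 100)
  aln <- translateAlignment(simulateAlignment(tr, prof))
  nRes <- apply(stateMatrix(aln), 2, function(col) length(unique(col)))
  expect_gt(cor(nRes, dN(prof), method = "spearman"), 0.5)
})

test_that("grid materialization is deterministic and resumable", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- gridConfig(branchLengths = 0.2, taxaCounts = 4, nSites = 6,
                    nReplicates = 2, masterSeed = 7)
  r1 <- generateGrid(cfg, dir1)
  r2 <- generateGrid(cfg, dir2)
  expect_equal(nrow(r1), 2)
  for (i in seq_len(nrow(r1))) {
    expect_identical(readLines(r1$fasta[i]), readLines(r2$fasta[i]))
    expect_identical(readLines(r1$truth[i]), readLines(r2$truth[i]))
  }
  # a partial run is rejected unless resumed
  expect_error(generateGrid(cfg, dir1), "resume")
  file.remove(r1$fasta[2])
  r3 <- generateGrid(cfg, dir1, resume = TRUE)
  expect_identical(readLines(r3$fasta[2]), readLines(r2$fasta[2]))
})

test_that("profile TSV serialization round-trips both profile kinds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(55)
  p <- drawProfiles("variable_dS", 15)
  writeProfiles(p, path)
  back <- readProfiles(path)
  expect_equal(dN(back), dN(p), tolerance = 1e-12)
  expect_equal(dS(back), dS(p), tolerance = 1e-12)
  pm <- drawProfiles("mutsel_codon_bias", 4)
  writeProfiles(pm, path)
  backM <- readProfiles(path, mutation = pm@mutation)
  expect_equal(backM@fitness, pm@fitness, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(trueDnDs(backM), trueDnDs(pm), tolerance = 1e-10)
})
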