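# Experimental-grid bookkeeping and materialization: tree grids, replicate
# registries, and on-disk generation of alignments with ground truth.

#' Construct a grid configuration
#'
#' Defaults describe the package's standard simulation study: branch
#' lengths 0.0025, 0.01, 0.04, 0.16, 0.64; 100 codon sites; 50 replicates
#' per cell; constant-dS regime over taxa counts 128-2048.
#'
#' @param branchLengths positive branch lengths.
#' @param taxaCounts powers of two.
#' @param nSites codon sites per alignment.
#' @param nReplicates replicates per (branch length, taxa) cell.
#' @param regime rate-drawing regime (see \code{\link{drawProfiles}}).
#' @param gammaShape,gammaRate gamma parameters (regime `"gamma"`).
#' @param masterSeed integer master seed; all replicate seeds derive from
#'   it deterministically.
#' @return A `GridConfig`.
#' @export
#' @examples
#' gridConfig(taxaCounts = c(16, 32), nReplicates = 2)
gridConfig <- function(branchLengths = c(0.0025, 0.01, 0.04, 0.16, 0.64),
                       taxaCounts = c(128, 256, 512, 1024, 2048),
                       nSites = 100, nReplicates = 50,
                       regime = "constant_dS",
                       gammaShape = 0.312, gammaRate = 1.027,
                       masterSeed = 1) {
  new("GridConfig", branchLengths = branchLengths, taxaCounts = taxaCounts,
      nSites = nSites, nReplicates = nReplicates, regime = regime,
      gammaShape = gammaShape, gammaRate = gammaRate,
      masterSeed = masterSeed)
}

#' The balanced-tree grid
#'
#' Enumerates (and optionally builds) one balanced tree per combination of
#' branch length and taxon count. The full default grid (5 branch lengths
#' x 8 taxa counts, 16 to 2,048 taxa) has 40 trees.
#'
#' @param branchLengths branch lengths of the grid.
#' @param taxaCounts taxon counts of the grid.
#' @param build if `TRUE`, attach the `phylo` objects in a list column.
#' @return data.frame with one row per tree (`branchLength`, `nTaxa`,
#'   `nEdges`, and `tree` when built).
#' @export
#' @examples
#' nrow(treeGrid())  # 40
treeGrid <- function(branchLengths = c(0.0025, 0.01, 0.04, 0.16, 0.64),
                     taxaCounts = 2^(4:11), build = FALSE) {
  g <- expand.grid(branchLength = branchLengths, nTaxa = taxaCounts,
                   KEEP.OUT.ATTRS = FALSE)
  g$nEdges <- 2L * g$nTaxa - 2L
  if (build) {
    g$tree <- lapply(seq_len(nrow(g)), function(i)
      makeBalancedTree(g$nTaxa[i], g$branchLength[i]))
  }
  g
}

#' Enumerate the replicate registry of a grid design
#'
#' Pure bookkeeping (no simulation): one row per replicate alignment of
#' each grid cell of each configuration, with its derived seed. The
#' standard uniform-rate design (constant plus variable dS, 50 replicates,
#' 5 branch lengths, taxa 128-2048) enumerates 2,500 alignments.
#'
#' @param configs a `GridConfig` or list of them.
#' @return data.frame with columns `regime`, `branchLength`, `nTaxa`,
#'   `replicate`, `seed`.
#' @export
#' @examples
#' nrow(gridRegistry(uniformRateDesign()))  # 2500
gridRegistry <- function(configs) {
  if (is(configs, "GridConfig")) configs <- list(configs)
  out <- lapply(configs, function(cfg) {
    cells <- expand.grid(branchLength = cfg@branchLengths,
                         nTaxa = cfg@taxaCounts, KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(cells)), function(ci) {
      data.frame(regime = cfg@regime,
                 branchLength = cells$branchLength[ci],
                 nTaxa = cells$nTaxa[ci],
                 replicate = seq_len(cfg@nReplicates),
                 seed = vapply(seq_len(cfg@nReplicates), function(r)
                   .deriveSeed(cfg@masterSeed, ci, r), integer(1)))
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' The standard uniform-rate study design
#'
#' Two configurations (constant and variable dS), each 50 replicates x 5
#' branch lengths x taxa counts 128-2048.
#'
#' @param masterSeed master seed shared by both configurations.
#' @return List of two `GridConfig` objects.
#' @export
uniformRateDesign <- function(masterSeed = 1) {
  list(gridConfig(regime = "constant_dS", masterSeed = masterSeed),
       gridConfig(regime = "variable_dS", masterSeed = masterSeed))
}

#' Materialize a simulation grid on disk
#'
#' Writes, per grid cell, the Newick tree and, per replicate, a FASTA
#' codon alignment plus a ground-truth TSV (`site`, `dN`, `dS`, `dnds`).
#' Deterministic for a given configuration: re-running with the same
#' master seed reproduces byte-identical files.
#'
#' @param config a `GridConfig`.
#' @param outDir output directory (created if needed).
#' @param resume if `FALSE` (default) a directory already holding a
#'   registry is rejected; if `TRUE`, existing replicate files are kept
#'   and only missing ones are generated.
#' @return The registry data.frame (invisibly also written to
#'   `registry.tsv`), with `fasta`, `truth`, `tree` path columns.
#' @export
generateGrid <- function(config, outDir, resume = FALSE) {
  stopifnot(is(config, "GridConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  regPath <- file.path(outDir, "registry.tsv")
  if (file.exists(regPath) && !resume)
    stop("output directory already contains a registry; ",
         "use resume = TRUE to fill in missing replicates")
  reg <- gridRegistry(config)
  tag <- function(bl, n) paste0("bl", format(bl, trim = TRUE), "_n", n)
  reg$tree <- file.path(outDir, paste0("tree_",
    tag(reg$branchLength, reg$nTaxa), ".nwk"))
  stem <- paste0(config@regime, "_", tag(reg$branchLength, reg$nTaxa),
                 "_rep", reg$replicate)
  reg$fasta <- file.path(outDir, paste0("aln_", stem, ".fasta"))
  reg$truth <- file.path(outDir, paste0("truth_", stem, ".tsv"))

  params <- list(gammaShape = config@gammaShape, gammaRate = config@gammaRate)
  for (i in seq_len(nrow(reg))) {
    tree <- makeBalancedTree(reg$nTaxa[i], reg$branchLength[i])
    if (!file.exists(reg$tree[i])) writeNewick(tree, reg$tree[i])
    if (resume && file.exists(reg$fasta[i]) && file.exists(reg$truth[i]))
      next
    set.seed(reg$seed[i])
    profile <- drawProfiles(config@regime, config@nSites, params)
    aln <- simulateAlignment(tree, profile)
    writeAlignmentFasta(aln, reg$fasta[i])
    ratio <- trueDnDs(profile)
    truth <- if (is(profile, "SiteRateProfile")) {
      data.frame(site = seq_len(config@nSites), dN = profile@dN,
                 dS = profile@dS, dnds = ratio)
    } else {
      data.frame(site = seq_len(config@nSites), dN = NA_real_,
                 dS = NA_real_, dnds = ratio)
    }
    write.table(truth, reg$truth[i], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(reg, regPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(reg)
}
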