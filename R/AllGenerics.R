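# Generics and accessors.

#' Number of taxa / sites in an alignment
#'
#' @param x a `CodonAlignment` or `AminoAcidAlignment`.
#' @return Integer count.
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname nTaxa
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Taxon labels of an alignment
#' @param x alignment object.
#' @return Character vector of labels.
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' State matrix of an alignment
#'
#' Returns the underlying taxa-by-sites character matrix (codons or
#' residues).
#' @param x alignment object.
#' @return Character matrix.
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @describeIn nTaxa rows of the codon matrix
setMethod("nTaxa", "CodonAlignment", function(x) nrow(x@codons))
#' @describeIn nTaxa rows of the residue matrix
setMethod("nTaxa", "AminoAcidAlignment", function(x) nrow(x@residues))
#' @describeIn nTaxa columns of the codon matrix
setMethod("nSites", "CodonAlignment", function(x) ncol(x@codons))
#' @describeIn nTaxa columns of the residue matrix
setMethod("nSites", "AminoAcidAlignment", function(x) ncol(x@residues))

setMethod("taxonNames", "CodonAlignment", function(x) rownames(x@codons))
setMethod("taxonNames", "AminoAcidAlignment", function(x) rownames(x@residues))
setMethod("stateMatrix", "CodonAlignment", function(x) x@codons)
setMethod("stateMatrix", "AminoAcidAlignment", function(x) x@residues)

#' Extract per-site scores from a RateEstimates object
#' @param x a `RateEstimates`.
#' @return Numeric vector of per-site scores.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
setMethod("scores", "RateEstimates", function(x) x@scores)

#' @describeIn scores kind of score (`"dnds"` or `"aa_rate"`)
#' @export
setGeneric("scoreKind", function(x) standardGeneric("scoreKind"))
setMethod("scoreKind", "RateEstimates", function(x) x@scoreKind)

#' @describeIn scores normalization state (`"raw"`, `"mean1"`, `"zscore"`)
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))
setMethod("normalization", "RateEstimates", function(x) x@normalization)

#' @describeIn scores list of method diagnostics
#' @export
setGeneric("estimateDetails", function(x) standardGeneric("estimateDetails"))
setMethod("estimateDetails", "RateEstimates", function(x) x@details)

#' Per-site dN, dS and their ratio from a rate profile
#'
#' @param x a `SiteRateProfile`.
#' @return Numeric vector, one value per site.
#' @export
setGeneric("dN", function(x) standardGeneric("dN"))
setMethod("dN", "SiteRateProfile", function(x) x@dN)

#' @rdname dN
#' @export
setGeneric("dS", function(x) standardGeneric("dS"))
setMethod("dS", "SiteRateProfile", function(x) x@dS)

#' @rdname dN
#' @export
setGeneric("dNdS", function(x) standardGeneric("dNdS"))
setMethod("dNdS", "SiteRateProfile", function(x) x@dN / x@dS)

#' @describeIn dN number of sites in a profile
setMethod("nSites", "SiteRateProfile", function(x) length(x@dN))
#' @describeIn dN number of sites in a mutation-selection profile
setMethod("nSites", "MutSelProfile", function(x) nrow(x@fitness))

#' Rate matrix accessors
#' @param x a `RateMatrix`.
#' @return `rateMatrix` returns the Q matrix; `stationary` its stationary
#'   distribution.
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))
setMethod("rateMatrix", "RateMatrix", function(x) x@Q)

#' @rdname rateMatrix
#' @export
setGeneric("stationary", function(x) standardGeneric("stationary"))
setMethod("stationary", "RateMatrix", function(x) x@stationary)

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", nTaxa(object), "taxa x", nSites(object),
      "codon sites\n")
})

setMethod("show", "AminoAcidAlignment", function(object) {
  cat("AminoAcidAlignment:", nTaxa(object), "taxa x", nSites(object),
      "sites\n")
})

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix:", nrow(object@Q), "states\n")
})

setMethod("show", "SiteRateProfile", function(object) {
  r <- dNdS(object)
  cat("SiteRateProfile:", nSites(object), "sites; dN/dS in [",
      signif(min(r), 3), ",", signif(max(r), 3), "]\n")
})

setMethod("show", "MutSelProfile", function(object) {
  cat("MutSelProfile:", nSites(object), "sites x", .NCODON,
      "codon fitnesses\n")
})

setMethod("show", "RateEstimates", function(object) {
  cat("RateEstimates (", object@scoreKind, ", ", object@normalization, "): ",
      length(object@scores), " sites\n", sep = "")
})

setMethod("show", "GridConfig", function(object) {
  cat("GridConfig:", object@regime, "regime;",
      length(object@branchLengths), "branch lengths x",
      length(object@taxaCounts), "taxa counts x",
      object@nReplicates, "replicates;", object@nSites, "sites\n")
})

setMethod("show", "AARateModel", function(object) {
  sh <- if (is.na(object@shape)) "estimated" else signif(object@shape, 4)
  cat("AARateModel:", object@name, "with", object@nCat,
      "gamma categories; shape:", sh, "\n")
})
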