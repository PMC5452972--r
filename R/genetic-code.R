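# Universal genetic code tables, precomputed once at install time from
# Biostrings::GENETIC_CODE. State space everywhere is the 61 sense codons
# in Biostrings order; stop codons (TAA, TAG, TGA) are excluded.

.GC <- Biostrings::GENETIC_CODE
.SENSE_CODONS <- names(.GC)[.GC != "*"]
.CODON_AA <- setNames(as.character(.GC[.SENSE_CODONS]), .SENSE_CODONS)
.NCODON <- length(.SENSE_CODONS)

# 61 x 61 logical masks for single-nucleotide neighbors, split by synonymy,
# plus the identity of the target (replacing) nucleotide of each change.
.codonTables <- local({
  n <- length(.SENSE_CODONS)
  mat <- do.call(rbind, strsplit(.SENSE_CODONS, ""))
  neighbor <- matrix(FALSE, n, n, dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  syn <- neighbor
  targetNuc <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) {
    diffs <- sweep(mat, 2, mat[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    nb <- which(ndiff == 1L)
    neighbor[i, nb] <- TRUE
    syn[i, nb] <- .CODON_AA[nb] == .CODON_AA[i]
    for (j in nb) targetNuc[i, j] <- mat[j, which(diffs[j, ])]
  }
  list(neighbor = neighbor, syn = syn & neighbor,
       nonsyn = neighbor & !syn, targetNuc = targetNuc,
       codonNuc = mat)
})

#' The sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons, in the fixed order used
#'   throughout the package (the row/column order of all codon rate matrices).
#' @export
#' @examples
#' length(senseCodons())
senseCodons <- function() .SENSE_CODONS

#' Translate codons to amino acids
#'
#' @param codons character vector of codons (3-letter DNA strings).
#' @return Character vector of one-letter amino-acid codes.
#' @export
#' @examples
#' translateCodons(c("ATG", "AAA"))
translateCodons <- function(codons) {
  bad <- !(codons %in% .SENSE_CODONS)
  if (any(bad)) {
    stop("not a sense codon: ", paste(unique(codons[bad]), collapse = ", "))
  }
  unname(.CODON_AA[codons])
}

#' Codon predicates of the universal code
#'
#' `isCodonNeighbor` tests whether two codons differ at exactly one
#' nucleotide position; `isSynonymousPair` additionally requires them to
#' encode the same amino acid.
#'
#' @param a,b codon strings (vectorized, recycled).
#' @return Logical vector.
#' @export
#' @examples
#' isCodonNeighbor("AAA", "AAG")   # TRUE
#' isSynonymousPair("AAA", "AAG")  # TRUE (both Lys)
isCodonNeighbor <- function(a, b) {
  ai <- match(a, .SENSE_CODONS)
  bi <- match(b, .SENSE_CODONS)
  if (anyNA(ai) || anyNA(bi)) stop("arguments must be sense codons")
  .codonTables$neighbor[cbind(ai, bi)]
}

#' @rdname isCodonNeighbor
#' @export
isSynonymousPair <- function(a, b) {
  ai <- match(a, .SENSE_CODONS)
  bi <- match(b, .SENSE_CODONS)
  if (anyNA(ai) || anyNA(bi)) stop("arguments must be sense codons")
  .codonTables$syn[cbind(ai, bi)]
}

# Amino-acid alphabet in the classical replacement-matrix (PAML) order;
# this is the state order of all 20x20 amino-acid matrices in the package.
.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
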