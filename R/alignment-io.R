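# Alignment constructors, FASTA I/O (via Biostrings), translation.

#' Construct alignments from state matrices or sequences
#'
#' `codonAlignment` accepts either a taxa-by-sites matrix of codons or a
#' named character vector of nucleotide sequences (lengths divisible by 3).
#'
#' @param x codon matrix with rownames, or named character vector of
#'   nucleotide sequence strings.
#' @return A `CodonAlignment`.
#' @export
#' @examples
#' codonAlignment(c(s1 = "ATGAAA", s2 = "ATGAAG"))
codonAlignment <- function(x) {
  if (is.matrix(x)) return(new("CodonAlignment", codons = x))
  if (!is.character(x) || is.null(names(x)))
    stop("x must be a codon matrix or a named character vector of sequences")
  w <- unique(nchar(x))
  if (length(w) != 1L)
    stop("ragged sequences: lengths ", paste(unique(nchar(x)), collapse = ", "))
  if (w == 0L) stop("empty sequences")
  if (w %% 3L != 0L)
    stop("sequence length ", w, " is not a multiple of 3")
  starts <- seq(1L, w, by = 3L)
  m <- t(vapply(x, function(s) substring(s, starts, starts + 2L),
                character(length(starts))))
  rownames(m) <- names(x)
  new("CodonAlignment", codons = m)
}

#' @rdname codonAlignment
#' @export
aminoAcidAlignment <- function(x) {
  if (is.matrix(x)) return(new("AminoAcidAlignment", residues = x))
  if (!is.character(x) || is.null(names(x)))
    stop("x must be a residue matrix or a named character vector of sequences")
  w <- unique(nchar(x))
  if (length(w) != 1L)
    stop("ragged sequences: lengths ", paste(unique(nchar(x)), collapse = ", "))
  if (w == 0L) stop("empty sequences")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  new("AminoAcidAlignment", residues = m)
}

#' Read and write alignments as FASTA
#'
#' Codon alignments are written as nucleotide FASTA; reading validates that
#' all sequences have equal length divisible by three and contain sense
#' codons only (stop codons are rejected).
#'
#' @param aln alignment object.
#' @param path FASTA file path.
#' @return Readers return the alignment object; writers return `path`
#'   invisibly.
#' @export
writeAlignmentFasta <- function(aln, path) {
  if (is(aln, "CodonAlignment")) {
    seqs <- apply(aln@codons, 1L, paste, collapse = "")
    set <- Biostrings::DNAStringSet(seqs)
  } else if (is(aln, "AminoAcidAlignment")) {
    seqs <- apply(aln@residues, 1L, paste, collapse = "")
    set <- Biostrings::AAStringSet(seqs)
  } else {
    stop("aln must be a CodonAlignment or AminoAcidAlignment")
  }
  names(set) <- taxonNames(aln)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname writeAlignmentFasta
#' @export
readCodonAlignment <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  seqs <- setNames(as.character(set), names(set))
  codonAlignment(seqs)
}

#' @rdname writeAlignmentFasta
#' @export
readAminoAcidAlignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  seqs <- setNames(as.character(set), names(set))
  aminoAcidAlignment(seqs)
}

#' Translate a codon alignment into amino acids
#'
#' Positionwise standard-code translation; the shape (taxa x sites) is
#' preserved.
#'
#' @param aln a `CodonAlignment`.
#' @return An `AminoAcidAlignment` of the same dimensions.
#' @export
#' @examples
#' aln <- codonAlignment(c(s1 = "ATGAAA", s2 = "ATGAAG"))
#' stateMatrix(translateAlignment(aln))
translateAlignment <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  m <- aln@codons
  res <- matrix(translateCodons(m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  new("AminoAcidAlignment", residues = res)
}
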