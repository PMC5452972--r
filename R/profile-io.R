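# TSV serialization of site rate profiles (ground-truth exchange format).

#' Read and write site profiles as TSV
#'
#' `SiteRateProfile` objects are stored with columns `site`, `dN`, `dS`;
#' `MutSelProfile` objects with `site` plus one fitness column per sense
#' codon (the mutation matrix is not stored and must be supplied on read).
#'
#' @param profile a `SiteRateProfile` or `MutSelProfile`.
#' @param path TSV file path.
#' @param mutation mutation matrix to attach when reading a fitness table
#'   (default \code{\link{mutationMatrix}()}).
#' @return `writeProfiles` returns `path` invisibly; `readProfiles`
#'   returns the profile object.
#' @export
writeProfiles <- function(profile, path) {
  if (is(profile, "SiteRateProfile")) {
    df <- data.frame(site = seq_len(nSites(profile)), dN = profile@dN,
                     dS = profile@dS)
  } else if (is(profile, "MutSelProfile")) {
    df <- data.frame(site = seq_len(nSites(profile)), profile@fitness,
                     check.names = FALSE)
  } else {
    stop("profile must be a SiteRateProfile or MutSelProfile")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path, mutation = mutationMatrix()) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (all(c("dN", "dS") %in% names(df)))
    return(siteRateProfile(dN = df$dN, dS = df$dS))
  codCols <- intersect(.SENSE_CODONS, names(df))
  if (length(codCols) == .NCODON) {
    return(mutSelProfile(as.matrix(df[, .SENSE_CODONS]), mutation))
  }
  stop("unrecognized profile table: expected columns dN/dS or 61 sense ",
       "codon fitness columns")
}
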