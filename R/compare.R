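# Comparison statistics between per-site score vectors: correlation, RMSD
# of mean-normalized scores, and replicate aggregation per grid cell.

.scoreVector <- function(x) {
  if (is(x, "RateEstimates")) return(x@scores)
  if (is.numeric(x)) return(as.numeric(x))
  stop("scores must be numeric or a RateEstimates object")
}

#' Correlation between two per-site score vectors
#'
#' @param a,b numeric vectors or `RateEstimates` of equal length >= 3.
#' @param method `"spearman"` (default; rank correlation is insensitive to
#'   the different normalizations of the two score kinds) or `"pearson"`.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` (with a warning)
#'   if either vector has zero variance.
#' @export
#' @examples
#' correlateScores(c(1, 2, 3, 4), c(1, 3, 2, 4))
correlateScores <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- .scoreVector(a); y <- .scoreVector(b)
  if (length(x) != length(y)) stop("score vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 sites to correlate")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("scores must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a score vector; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = method)
}

#' RMSD between two mean-normalized score vectors
#'
#' Root-mean-square deviation between per-site scores. Both inputs must be
#' in mean-1 normalization (the comparability condition for scores
#' measured in different units); numeric vectors are accepted if their
#' mean is 1.
#'
#' @param a,b mean-normalized `RateEstimates` or numeric vectors of equal
#'   length.
#' @return Nonnegative RMSD.
#' @export
#' @examples
#' scoreRMSD(c(0.5, 1.5), c(1.5, 0.5))  # 1
scoreRMSD <- function(a, b) {
  checkMean1 <- function(z, label) {
    if (is(z, "RateEstimates")) {
      if (z@normalization != "mean1")
        stop(label, " is not mean-1 normalized (found '",
             z@normalization, "'); apply normalizeScores(, 'mean1') first")
    } else if (abs(mean(.scoreVector(z)) - 1) > 1e-6) {
      stop(label, " is not mean-1 normalized (mean = ",
           signif(mean(.scoreVector(z)), 6), ")")
    }
  }
  checkMean1(a, "first score vector")
  checkMean1(b, "second score vector")
  x <- .scoreVector(a); y <- .scoreVector(b)
  if (length(x) != length(y)) stop("score vectors differ in length")
  sqrt(mean((x - y)^2))
}

#' Aggregate replicate comparison results per grid cell
#'
#' Computes, per (regime, branchLength, nTaxa, comparison) cell, the mean
#' and standard error (sd / sqrt(n)) of each statistic over replicates.
#' Undefined replicate values (NA correlations from zero-variance score
#' vectors) are dropped and counted.
#'
#' @param results data.frame as produced by \code{\link{runStudy}} (one
#'   row per replicate and comparison, with `pearson`, `spearman`, `rmsd`
#'   columns).
#' @return data.frame with one row per cell x statistic: `mean`, `se`,
#'   `nUsed`, `nDropped`, and a `singleReplicate` flag (SE reported as 0
#'   when only one replicate is available).
#' @export
aggregateComparisons <- function(results) {
  stopifnot(is.data.frame(results))
  stats <- intersect(c("pearson", "spearman", "rmsd"), names(results))
  keys <- intersect(c("regime", "branchLength", "nTaxa", "comparison"),
                    names(results))
  if (length(keys) == 0L) stop("results lack grid cell identifier columns")
  cellId <- interaction(results[keys], drop = TRUE)
  out <- lapply(levels(cellId), function(lev) {
    block <- results[cellId == lev, , drop = FALSE]
    rows <- lapply(stats, function(st) {
      v <- block[[st]]
      used <- v[is.finite(v)]
      n <- length(used)
      if (n == 0L) {
        warning("cell ", lev, ": no usable replicate values for ", st)
        return(NULL)
      }
      data.frame(block[1L, keys, drop = FALSE], statistic = st,
                 mean = mean(used),
                 se = if (n > 1L) sd(used) / sqrt(n) else 0,
                 nUsed = n, nDropped = length(v) - n,
                 singleReplicate = n == 1L, row.names = NULL)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
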