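# Empirical-Bayes site-specific relative rates on amino-acid alignments:
# per-site posterior mean rate over K discretized gamma categories under an
# empirical replacement matrix, with the gamma shape fitted by maximizing
# the whole-alignment likelihood.

# Exchangeabilities and equilibrium frequencies of the classical empirical
# replacement models, taken from phangorn's model tables (stored lower
# triangle, PAML residue order ARNDCQEGHILKMFPSTWYV).
.aaModelTable <- function(name) {
  obj <- tryCatch(getFromNamespace(paste0(".", name), "phangorn"),
                  error = function(e) NULL)
  if (is.null(obj) || is.null(obj$Q) || is.null(obj$bf))
    stop("replacement matrix '", name, "' not available")
  S <- matrix(0, 20L, 20L, dimnames = list(.AA_ORDER, .AA_ORDER))
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  bf <- as.numeric(obj$bf)
  list(S = S, freqs = setNames(bf / sum(bf), .AA_ORDER))
}

#' Construct an amino-acid rate model
#'
#' An empirical reversible replacement process plus a discretized gamma
#' prior over site rates. Category rates are equal-probability quantile
#' midpoints of the gamma distribution, rescaled to prior mean 1.
#'
#' @param matrix replacement matrix name: `"JTT"` (default), `"LG"` or
#'   `"WAG"`.
#' @param nCat number of gamma categories (default 16).
#' @param shape gamma shape; `NULL` (default) means estimate by maximum
#'   likelihood per alignment (empirical Bayes).
#' @return An `AARateModel`.
#' @export
#' @examples
#' aaRateModel("JTT", nCat = 8)
aaRateModel <- function(matrix = c("JTT", "LG", "WAG"), nCat = 16,
                        shape = NULL) {
  name <- match.arg(matrix)
  tab <- .aaModelTable(name)
  new("AARateModel", name = name, exchangeability = tab$S,
      freqs = tab$freqs, nCat = nCat,
      shape = if (is.null(shape)) NA_real_ else shape)
}

# Mean-rate-1 replacement rate matrix of a model.
.aaQ <- function(model) {
  Q <- model@exchangeability * rep(model@freqs, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(model@freqs * rowSums(model@exchangeability *
                                       rep(model@freqs, each = 20L)))
  dimnames(Q) <- list(.AA_ORDER, .AA_ORDER)
  Q
}

# Equal-probability quantile-midpoint discretization, rescaled to mean 1.
.gammaCategoryRates <- function(shape, nCat) {
  r <- qgamma((seq_len(nCat) - 0.5) / nCat, shape = shape, rate = shape)
  r / mean(r)
}

#' Site-specific relative rates by empirical Bayes
#'
#' For each site, computes the likelihood of the column under the
#' rate-multiplied replacement process `exp(r Q t)` at each of `nCat`
#' discretized gamma category rates, and returns the posterior mean rate.
#' Unless the model fixes it, the gamma shape is first fitted by
#' maximizing the summed column log-likelihoods over the whole alignment.
#' Branch lengths are taken as given; a global scale mismatch between tree
#' units and amino-acid substitutions is absorbed by the downstream mean-1
#' normalization of the scores.
#'
#' @param aln an `AminoAcidAlignment`; `-`/`X` are treated as missing.
#' @param tree ape `phylo` whose tip labels match the alignment taxa.
#' @param model an \code{\link{aaRateModel}}.
#' @param shapeBounds search interval for the gamma shape (default
#'   `c(0.05, 20)`).
#' @return A `RateEstimates` with `scoreKind = "aa_rate"`,
#'   `normalization = "raw"`, strictly positive scores.
#'   `estimateDetails()` carries the fitted shape and category rates.
#' @export
#' @examples
#' set.seed(5)
#' tr <- makeBalancedTree(8, 0.3)
#' aln <- translateAlignment(simulateAlignment(tr, drawProfiles("constant_dS", 15)))
#' est <- aaRates(aln, tr, aaRateModel(nCat = 8))
#' head(scores(est))
aaRates <- function(aln, tree, model = aaRateModel(),
                    shapeBounds = c(0.05, 20)) {
  stopifnot(is(aln, "AminoAcidAlignment"), inherits(tree, "phylo"),
            is(model, "AARateModel"))
  if (!setequal(taxonNames(aln), tree$tip.label))
    stop("alignment taxa and tree tip labels do not match")
  m <- aln@residues[tree$tip.label, , drop = FALSE]
  stateIdx <- .encodeStates(m, .AA_ORDER)  # '-'/'X' become NA (missing)
  nS <- ncol(stateIdx)
  Q <- .aaQ(model)
  nCat <- as.integer(model@nCat)
  baseFactory <- .transitionFactory(Q, model@freqs)

  rateLogLik <- function(r) {
    Pfun <- function(t) baseFactory(r * t)
    .pruneLogLik(stateIdx, tree, Pfun, model@freqs, 20L)
  }
  catLogLik <- function(shape) {
    rates <- .gammaCategoryRates(shape, nCat)
    ll <- do.call(rbind, lapply(rates, rateLogLik))
    list(rates = rates, ll = ll)
  }
  totalLogLik <- function(ll) {
    mx <- apply(ll, 2L, max)
    sum(mx + log(colMeans(exp(ll - rep(mx, each = nrow(ll))))))
  }

  if (is.na(model@shape)) {
    # The per-category likelihood depends on the shape only through the
    # category rates, so precompute site log-likelihoods on a fixed rate
    # grid once and fit the shape on log-rate-interpolated values; the
    # grid is log-dense where the likelihood curves, and the low-rate tail
    # (where log-likelihood is asymptotically linear in log rate) is
    # covered coarsely.
    rGrid <- c(exp(seq(log(1e-12), log(1e-3), length.out = 6L))[-6L],
               exp(seq(log(1e-3), log(nCat + 1), length.out = 28L)))
    lg <- log(rGrid)
    llR <- do.call(rbind, lapply(rGrid, rateLogLik))
    interpLL <- function(rates) {
      x <- pmin(pmax(log(rates), lg[1L]), lg[length(lg)])
      g <- pmin(findInterval(x, lg), length(lg) - 1L)
      w <- (x - lg[g]) / (lg[g + 1L] - lg[g])
      (1 - w) * llR[g, , drop = FALSE] + w * llR[g + 1L, , drop = FALSE]
    }
    opt <- optimize(function(a)
      totalLogLik(interpLL(.gammaCategoryRates(a, nCat))),
      interval = shapeBounds, maximum = TRUE, tol = 1e-2)
    shape <- opt$maximum
  } else {
    shape <- model@shape
  }
  fit <- catLogLik(shape)
  w <- exp(fit$ll - rep(apply(fit$ll, 2L, max), each = nCat))
  post <- colSums(w * fit$rates) / colSums(w)

  new("RateEstimates", scores = as.numeric(post), scoreKind = "aa_rate",
      normalization = "raw",
      details = list(shape = shape, categoryRates = fit$rates,
                     logLik = apply(fit$ll, 2L, max)))
}

#' Normalize per-site rate scores
#'
#' `mean1` divides every score by the arithmetic mean across sites (the
#' natural normalization for comparing score kinds measured in different
#' units); `zscore` centers and scales to unit standard deviation.
#' `mean1` is idempotent.
#'
#' @param est a `RateEstimates`.
#' @param mode `"mean1"` or `"zscore"`.
#' @return A `RateEstimates` with updated scores and normalization flag.
#' @export
#' @examples
#' est <- new("RateEstimates", scores = c(1, 2, 3), scoreKind = "aa_rate",
#'            normalization = "raw")
#' scores(normalizeScores(est, "mean1"))  # 0.5 1.0 1.5
normalizeScores <- function(est, mode = c("mean1", "zscore")) {
  stopifnot(is(est, "RateEstimates"))
  mode <- match.arg(mode)
  x <- est@scores
  if (mode == "mean1") {
    mu <- mean(x)
    if (!is.finite(mu) || mu == 0)
      stop("cannot mean-normalize: score mean is ", mu)
    x <- x / mu
  } else {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("cannot z-normalize: score standard deviation is ", s)
    x <- (x - mean(x)) / s
  }
  new("RateEstimates", scores = x, scoreKind = est@scoreKind,
      normalization = mode, details = est@details)
}
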