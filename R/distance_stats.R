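# Histogram, peak and observed-versus-null statistics for pooled pair
# distances.

# shared binning: half-open [k*w, (k+1)*w), last bin closed on the right
.binIndices <- function(d, binWidth, nBins) {
  pmin(floor(d / binWidth) + 1L, nBins)
}

.nBinsFor <- function(maxD, binWidth) {
  max(1L, as.integer(ceiling(maxD / binWidth)))
}

#' Bin pooled pair distances into a fixed-width histogram
#'
#' Bins are half-open `[k*w, (k+1)*w)` starting at zero; the last bin is
#' closed on the right so the sample maximum is always covered.
#'
#' @param distances numeric vector of non-negative distances (Angstrom); a
#'   [PairingResult] is also accepted.
#' @param binWidth bin width in Angstrom (default 20).
#' @param label `"observed"` or `"null"`.
#' @return a [DistanceDistribution]; empty input yields an empty distribution
#'   (`nTotal = 0`) with a warning.
#' @examples
#' binCounts(distanceHistogram(c(5, 15, 15), binWidth = 10))  # 1 2
#' @export
distanceHistogram <- function(distances, binWidth = 20, label = "observed") {
  if (is(distances, "PairingResult")) distances <- pairDistances(distances)
  stopifnot(binWidth > 0)
  if (length(distances) == 0L) {
    warning("empty distance list; returning an empty distribution")
    return(new("DistanceDistribution", binWidth = binWidth, breaks = 0,
               counts = integer(0), label = label, nTotal = 0L))
  }
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative")
  nb <- .nBinsFor(max(distances), binWidth)
  counts <- tabulate(.binIndices(distances, binWidth, nb), nbins = nb)
  new("DistanceDistribution", binWidth = binWidth,
      breaks = seq(0, by = binWidth, length.out = nb + 1L),
      counts = as.integer(counts), label = label,
      nTotal = length(distances))
}

#' Histogram mode of a distance distribution
#'
#' The peak readout of the pairing analysis: the center of the maximal-count
#' bin. Ties are resolved toward the smallest center.
#'
#' @param x a [DistanceDistribution]
#' @return mode location in Angstrom
#' @export
setGeneric("modeEstimate", function(x) standardGeneric("modeEstimate"))

#' @export
setMethod("modeEstimate", "DistanceDistribution", function(x) {
  if (x@nTotal == 0L)
    stop("mode is undefined for an empty distribution")
  binCenters(x)[which.max(x@counts)]
})

#' Kernel-density peak of raw distances
#'
#' Smoothness check alternative to the binned [modeEstimate()]: location of
#' the maximum of a Gaussian kernel density estimate of the raw distances.
#'
#' @param distances numeric vector (Angstrom).
#' @param bw bandwidth passed to [stats::density()].
#' @return peak location in Angstrom
#' @export
kdeModeEstimate <- function(distances, bw = "nrd0") {
  if (length(distances) < 2L) stop("need at least 2 distances for a KDE")
  den <- stats::density(distances, bw = bw, from = 0)
  den$x[which.max(den$y)]
}

#' Compare observed pair distances with a randomized null
#'
#' Bins both samples on a shared grid spanning both maxima and reports the
#' per-bin excess `observed - mean(null)`, the two-sample Kolmogorov-Smirnov
#' statistic between the raw samples, and the bin center of the maximal
#' excess. When the null consists of several replicates (a list of distance
#' vectors), null counts are averaged per bin - not concatenated - so the
#' excess stays on the observed count scale; the KS statistic is computed
#' against the concatenated null sample.
#'
#' @param observed numeric vector of observed distances (or a
#'   [PairingResult]).
#' @param null numeric vector, list of numeric vectors (replicates), or a
#'   [PairingResult].
#' @param binWidth bin width in Angstrom (default 20).
#' @return a [NullComparison]
#' @export
compareToNull <- function(observed, null, binWidth = 20) {
  if (is(observed, "PairingResult")) observed <- pairDistances(observed)
  if (is(null, "PairingResult")) null <- pairDistances(null)
  if (!is.list(null)) null <- list(null)
  if (length(observed) == 0L)
    stop("observed sample is empty")
  if (sum(lengths(null)) == 0L)
    stop("null sample is empty")
  stopifnot(binWidth > 0)
  nullPooled <- unlist(null, use.names = FALSE)
  nb <- .nBinsFor(max(observed, nullPooled), binWidth)
  oc <- tabulate(.binIndices(observed, binWidth, nb), nbins = nb)
  ncMat <- vapply(null, function(v)
    tabulate(.binIndices(v, binWidth, nb), nbins = nb), numeric(nb))
  ncMean <- rowMeans(matrix(ncMat, nrow = nb))
  excess <- oc - ncMean
  ks <- unname(suppressWarnings(
    stats::ks.test(observed, nullPooled)$statistic))
  centers <- seq(0, by = binWidth, length.out = nb) + binWidth / 2
  new("NullComparison", binWidth = binWidth,
      breaks = seq(0, by = binWidth, length.out = nb + 1L),
      observedCounts = as.integer(oc), nullMeanCounts = ncMean,
      excess = excess, ksStatistic = ks,
      excessPeakA = centers[which.max(excess)],
      nObserved = length(observed),
      nNullMean = mean(lengths(null)),
      nNullReplicates = length(null))
}

#' Two-sample Kolmogorov-Smirnov critical value
#'
#' Large-sample critical value `c(alpha) * sqrt((n + m) / (n * m))` with
#' `c(alpha) = sqrt(-log(alpha / 2) / 2)`, above which the two-sample KS
#' statistic rejects equality of distributions at level `alpha`.
#'
#' @param n,m the two sample sizes.
#' @param alpha significance level (default 0.01).
#' @return the critical KS statistic
#' @export
ksCriticalValue <- function(n, m, alpha = 0.01) {
  stopifnot(n > 0, m > 0, alpha > 0, alpha < 1)
  sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
}

#' Bootstrap percentile interval for the histogram mode
#'
#' Nonparametric uncertainty on the peak location: the 95% percentile
#' interval of [modeEstimate()] over bootstrap resamples of the distances.
#'
#' @param distances numeric vector, length >= 10.
#' @param binWidth bin width in Angstrom (default 20).
#' @param nBoot number of bootstrap resamples (default 200).
#' @param seed integer seed (resampling is deterministic given it).
#' @return numeric length-2 vector `c(lo, hi)` in Angstrom
#' @export
bootstrapModeCI <- function(distances, binWidth = 20, nBoot = 200L,
                            seed = 1L) {
  n <- length(distances)
  if (n < 10L)
    stop("need at least 10 distances for a bootstrap interval (got ", n, ")")
  stopifnot(nBoot >= 1L)
  set.seed(seed)
  modes <- vapply(seq_len(nBoot), function(b) {
    res <- distances[sample.int(n, n, replace = TRUE)]
    modeEstimate(distanceHistogram(res, binWidth))
  }, numeric(1))
  unname(stats::quantile(modes, c(0.025, 0.975), type = 7))
}
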