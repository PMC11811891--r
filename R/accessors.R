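#' @describeIn ParticleSet number of particle records
#' @param x,object a `ParticleSet`
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @export
setMethod("nParticles", "ParticleSet", function(x) nrow(x@particles))

#' @describeIn ParticleSet unique micrograph identifiers (sorted)
#' @export
setGeneric("micrographNames", function(x) standardGeneric("micrographNames"))

#' @export
setMethod("micrographNames", "ParticleSet",
          function(x) sort(unique(x@particles$micrograph)))

#' @describeIn ParticleSet population label
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @export
setMethod("population", "ParticleSet", function(x) x@population)

#' @describeIn ParticleSet pixel size in Angstrom per pixel
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setMethod("pixelSize", "ParticleSet", function(x) x@pixelSize)

#' @describeIn ParticleSet the raw particle record table (one row per particle)
#' @export
setGeneric("particleData", function(x) standardGeneric("particleData"))

#' @export
setMethod("particleData", "ParticleSet", function(x) x@particles)

setMethod("show", "ParticleSet", function(object) {
  cat("ParticleSet '", object@population, "': ", nrow(object@particles),
      " particles in ", length(unique(object@particles$micrograph)),
      " micrograph(s), ", format(object@pixelSize), " A/px\n", sep = "")
})

#' Pooled pair distances of a PairingResult
#'
#' Distances are returned micrograph by micrograph (micrographs in sorted
#' order), within each micrograph in greedy selection order, i.e. the order in
#' which the delete-minimum loop assigned them.
#'
#' @param x a `PairingResult`
#' @return numeric vector of distances in Angstrom
#' @export
setGeneric("pairDistances", function(x) standardGeneric("pairDistances"))

#' @export
setMethod("pairDistances", "PairingResult", function(x) x@pairs$distance)

#' @describeIn PairingResult per-pair table (micrograph, rowIdx, colIdx, distance)
#' @param x a `PairingResult`
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @export
setMethod("pairTable", "PairingResult", function(x) x@pairs)

#' @describeIn PairingResult micrographs present in only one input table
#' @export
setGeneric("skippedMicrographs", function(x) standardGeneric("skippedMicrographs"))

#' @export
setMethod("skippedMicrographs", "PairingResult", function(x) x@skippedMicrographs)

setMethod("show", "PairingResult", function(object) {
  cat("PairingResult: ", nrow(object@pairs), " pairs across ",
      object@nSharedMicrographs, " shared micrograph(s); ",
      length(object@skippedMicrographs), " skipped\n", sep = "")
})

#' @describeIn DistanceDistribution bin centers in Angstrom
#' @param x,object a `DistanceDistribution`
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @export
setMethod("binCenters", "DistanceDistribution", function(x) {
  if (length(x@counts) == 0L) return(numeric(0))
  (head(x@breaks, -1L) + x@binWidth / 2)
})

#' @describeIn DistanceDistribution per-bin counts
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @export
setMethod("binCounts", "DistanceDistribution", function(x) x@counts)

setMethod("show", "DistanceDistribution", function(object) {
  if (object@nTotal == 0L) {
    cat("DistanceDistribution (", object@label, "): empty\n", sep = "")
  } else {
    cat("DistanceDistribution (", object@label, "): n = ", object@nTotal,
        ", ", length(object@counts), " bins of ", format(object@binWidth),
        " A, range [0, ", format(max(object@breaks)), ") A\n", sep = "")
  }
})

#' @describeIn NullComparison Kolmogorov-Smirnov statistic between the raw samples
#' @param x,object a `NullComparison`
#' @export
setGeneric("ksStatistic", function(x) standardGeneric("ksStatistic"))

#' @export
setMethod("ksStatistic", "NullComparison", function(x) x@ksStatistic)

#' @describeIn NullComparison bin center of the maximal observed-minus-null excess
#' @export
setGeneric("excessPeak", function(x) standardGeneric("excessPeak"))

#' @export
setMethod("excessPeak", "NullComparison", function(x) x@excessPeakA)

#' @describeIn NullComparison per-bin excess counts (observed minus mean null)
#' @export
setGeneric("excessCounts", function(x) standardGeneric("excessCounts"))

#' @export
setMethod("excessCounts", "NullComparison", function(x) x@excess)

setMethod("show", "NullComparison", function(object) {
  cat("NullComparison: n_obs = ", object@nObserved, ", mean n_null = ",
      format(object@nNullMean), " (", object@nNullReplicates,
      " replicate(s)); KS = ", format(object@ksStatistic, digits = 4),
      "; excess peak at ", format(object@excessPeakA), " A\n", sep = "")
})

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams: ", object@nMicrographs, " micrograph(s) of ",
      format(object@fieldWA), " x ", format(object@fieldHA), " A; ",
      object@pairsPerMicrograph, " tethered pair(s) (sigma = ",
      format(object@tetherSigmaA), " A), free A/B = ",
      object@freeAPerMicrograph, "/", object@freeBPerMicrograph,
      ", detection = ", format(object@detectProbA), "/",
      format(object@detectProbB), ", seed = ", object@seed, "\n", sep = "")
})

#' @describeIn HillFit fitted dissociation constant in nM
#' @param x,object a `HillFit`
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))

#' @export
setMethod("kd", "HillFit", function(x) x@kdNM)

#' @describeIn HillFit normalized bound fractions (clipped to \[0, 1\])
#' @export
setGeneric("fractionBound", function(x) standardGeneric("fractionBound"))

#' @export
setMethod("fractionBound", "HillFit", function(x) x@fractionBound)

setMethod("show", "HillFit", function(object) {
  if (object@converged) {
    cat("HillFit (n = 1): Kd = ", format(object@kdNM, digits = 6),
        " nM, plateau = ", format(object@plateau, digits = 6),
        ", RSS = ", format(object@residualSS, digits = 4), "\n", sep = "")
  } else {
    cat("HillFit: FAILED -", object@message, "\n")
  }
})

setMethod("show", "DuplexSequence", function(object) {
  cat("DuplexSequence: ", object@lengthBp, " bp\n  nontemplate 5'-",
      object@nontemplate, "-3'\n  template    3'-",
      paste(rev(strsplit(object@template, "")[[1]]), collapse = ""),
      "-5'\n", sep = "")
})

#' @describeIn AlignmentProfile number of alignment columns
#' @param x,object an `AlignmentProfile`
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @export
setMethod("nColumns", "AlignmentProfile", function(x) ncol(x@counts))

#' @describeIn AlignmentProfile per-column symbol count matrix
#' @export
setGeneric("columnCounts", function(x) standardGeneric("columnCounts"))

#' @export
setMethod("columnCounts", "AlignmentProfile", function(x) x@counts)

setMethod("show", "AlignmentProfile", function(object) {
  cat("AlignmentProfile (", object@alphabet, "): ", object@nSequences,
      " sequences x ", ncol(object@counts), " columns\n", sep = "")
})
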