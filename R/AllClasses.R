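#' @import methods
NULL

#' ParticleSet: refined 2D particle coordinates for one population
#'
#' Holds one population of picked/refined single-particle coordinates, grouped
#' by micrograph. Picked coordinates are stored in pixels together with the
#' refinement origin shifts in Angstrom; the refined physical position is
#' `x_px * pixelSize - originX_A` (and likewise in y), following the RELION
#' convention for 2D coordinates plus `OriginX/YAngst` shifts.
#'
#' @slot particles data.frame with columns `micrograph` (character), `xPx`,
#'   `yPx` (picked coordinate, pixels), `originXA`, `originYA` (origin shift,
#'   Angstrom; 0 when the refinement supplied none).
#' @slot pixelSize numeric(1), Angstrom per pixel (> 0).
#' @slot population character(1) label, e.g. `"tauA"` or `"tauB"`.
#'
#' @seealso [readParticles()], [refinedPositions()], [writeParticles()]
#' @export
setClass("ParticleSet",
  representation(
    particles = "data.frame",
    pixelSize = "numeric",
    population = "character"
  )
)

setValidity("ParticleSet", function(object) {
  p <- object@particles
  need <- c("micrograph", "xPx", "yPx", "originXA", "originYA")
  if (!all(need %in% names(p)))
    return(paste("particles must have columns:", paste(need, collapse = ", ")))
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive finite number")
  if (length(object@population) != 1L)
    return("population must be a single label")
  if (nrow(p) > 0L) {
    if (!is.character(p$micrograph))
      return("micrograph column must be character")
    num <- c("xPx", "yPx", "originXA", "originYA")
    for (cn in num) {
      if (!is.numeric(p[[cn]])) return(paste(cn, "must be numeric"))
      if (any(!is.finite(p[[cn]]))) return(paste(cn, "contains non-finite values"))
    }
    if (any(p$xPx < 0) || any(p$yPx < 0))
      return("picked coordinates must be non-negative")
  }
  TRUE
})

#' PairingResult: greedy pair assignments across micrographs
#'
#' Result of [pairAllMicrographs()]: one row per matched particle pair, in
#' selection order within each micrograph. Row indices refer to the first
#' (tau-B) table's per-micrograph particle order, column indices to the second
#' (tau-A) table's.
#'
#' @slot pairs data.frame with columns `micrograph`, `rowIdx`, `colIdx`,
#'   `distance` (Angstrom).
#' @slot skippedMicrographs character, micrograph ids present in only one of
#'   the two input tables (contribute no pairs).
#' @slot nSharedMicrographs integer(1).
#' @export
setClass("PairingResult",
  representation(
    pairs = "data.frame",
    skippedMicrographs = "character",
    nSharedMicrographs = "integer"
  )
)

setValidity("PairingResult", function(object) {
  p <- object@pairs
  need <- c("micrograph", "rowIdx", "colIdx", "distance")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) > 0L) {
    if (any(p$distance < 0)) return("pair distances must be non-negative")
    dup <- vapply(split(p, p$micrograph), function(g) {
      anyDuplicated(g$rowIdx) > 0L || anyDuplicated(g$colIdx) > 0L
    }, logical(1))
    if (any(dup)) return("a particle index is paired more than once in a micrograph")
  }
  TRUE
})

#' DistanceDistribution: binned pair-distance histogram
#'
#' Half-open bins `[k*w, (k+1)*w)` of constant width `w` starting at zero; the
#' last bin is closed on the right so the sample maximum is always covered.
#'
#' @slot binWidth numeric(1), Angstrom.
#' @slot breaks numeric, increasing bin edges starting at 0.
#' @slot counts integer, one per bin.
#' @slot label character(1), `"observed"` or `"null"`.
#' @slot nTotal integer(1), total number of binned distances.
#' @export
setClass("DistanceDistribution",
  representation(
    binWidth = "numeric",
    breaks = "numeric",
    counts = "integer",
    label = "character",
    nTotal = "integer"
  )
)

setValidity("DistanceDistribution", function(object) {
  if (object@binWidth <= 0) return("binWidth must be positive")
  if (length(object@breaks) != length(object@counts) + 1L)
    return("breaks must have one more element than counts")
  if (length(object@breaks) && object@breaks[1] != 0)
    return("breaks must start at 0")
  if (is.unsorted(object@breaks, strictly = TRUE))
    return("breaks must be strictly increasing")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@nTotal)
    return("counts must sum to nTotal")
  TRUE
})

#' NullComparison: observed pair distances against a randomized null
#'
#' Per-bin excess of observed counts over the mean null counts (same binning),
#' the two-sample Kolmogorov-Smirnov statistic between the raw distance
#' samples, and the bin-center location of the maximal excess.
#'
#' @slot binWidth numeric(1), Angstrom.
#' @slot breaks numeric, shared bin edges spanning both samples.
#' @slot observedCounts integer per bin.
#' @slot nullMeanCounts numeric per bin (mean over null replicates).
#' @slot excess numeric per bin, `observedCounts - nullMeanCounts`.
#' @slot ksStatistic numeric(1) in \[0, 1\].
#' @slot excessPeakA numeric(1), center (Angstrom) of the maximal-excess bin.
#' @slot nObserved integer(1); `nNullMean` numeric(1): mean null sample size
#'   per replicate.
#' @slot nNullMean numeric(1).
#' @slot nNullReplicates integer(1).
#' @export
setClass("NullComparison",
  representation(
    binWidth = "numeric",
    breaks = "numeric",
    observedCounts = "integer",
    nullMeanCounts = "numeric",
    excess = "numeric",
    ksStatistic = "numeric",
    excessPeakA = "numeric",
    nObserved = "integer",
    nNullMean = "numeric",
    nNullReplicates = "integer"
  )
)

setValidity("NullComparison", function(object) {
  nb <- length(object@breaks) - 1L
  if (length(object@observedCounts) != nb || length(object@nullMeanCounts) != nb ||
      length(object@excess) != nb)
    return("per-bin vectors must match the number of bins")
  if (object@ksStatistic < 0 || object@ksStatistic > 1)
    return("ksStatistic must lie in [0, 1]")
  # conservation: total excess equals n_obs - mean n_null
  if (abs(sum(object@excess) - (object@nObserved - object@nNullMean)) > 1e-6)
    return("total excess must equal nObserved - nNullMean")
  TRUE
})

#' SceneParams: generative parameters for synthetic tethered-particle scenes
#'
#' Describes micrograph fields containing tethered A-B particle pairs plus
#' unlinked background particles. Each pair anchor is uniform in the field;
#' the partner sits at the anchor plus a 3D isotropic Gaussian displacement
#' (per-axis sd `tetherSigmaA`) projected to the image plane, so the true
#' projected pair separation is Rayleigh with mode `tetherSigmaA`.
#'
#' Defaults reproduce a sparse single-particle dataset: 100 micrographs of
#' 20 tethered pairs (tether scale 200 Angstrom) plus 10 unlinked particles
#' of each species, each particle retained with probability 0.9, on a
#' 11210 x 7965 Angstrom field at 0.822 Angstrom per pixel. The field extent
#' is set so the per-species particle density matches a typical refined
#' single-particle dataset (about 3e-7 particles per square Angstrom); see
#' the methods vignette.
#'
#' @slot fieldWA,fieldHA field extent in Angstrom (> 0).
#' @slot nMicrographs integer >= 1.
#' @slot pairsPerMicrograph integer >= 0, tethered pairs per micrograph.
#' @slot tetherSigmaA numeric >= 0, per-axis tether displacement sd (Angstrom).
#' @slot freeAPerMicrograph,freeBPerMicrograph integers >= 0, unlinked
#'   background particles per micrograph.
#' @slot detectProbA,detectProbB detection probability per emitted particle.
#' @slot pixelSizeA numeric > 0, Angstrom per pixel for STAR export.
#' @slot seed integer, master seed; per-micrograph substreams are derived
#'   from it.
#' @seealso [sceneParams()], [simulateScene()]
#' @export
setClass("SceneParams",
  representation(
    fieldWA = "numeric",
    fieldHA = "numeric",
    nMicrographs = "integer",
    pairsPerMicrograph = "integer",
    tetherSigmaA = "numeric",
    freeAPerMicrograph = "integer",
    freeBPerMicrograph = "integer",
    detectProbA = "numeric",
    detectProbB = "numeric",
    pixelSizeA = "numeric",
    seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  if (object@fieldWA <= 0 || object@fieldHA <= 0)
    return("field extents must be positive")
  if (object@nMicrographs < 1L) return("nMicrographs must be >= 1")
  if (object@pairsPerMicrograph < 0L || object@freeAPerMicrograph < 0L ||
      object@freeBPerMicrograph < 0L)
    return("particle counts must be non-negative")
  if (object@tetherSigmaA < 0) return("tetherSigmaA must be >= 0")
  for (p in c(object@detectProbA, object@detectProbB))
    if (p < 0 || p > 1) return("detection probabilities must lie in [0, 1]")
  if (object@pixelSizeA <= 0) return("pixelSizeA must be positive")
  TRUE
})

#' BindingCurve: filter-binding measurements over a concentration series
#'
#' @slot concentrationNM numeric, protein concentrations in nM, strictly
#'   increasing and positive.
#' @slot counts numeric, raw retained-signal values (non-negative).
#' @seealso [bindingCurve()], [fitBinding()]
#' @export
setClass("BindingCurve",
  representation(concentrationNM = "numeric", counts = "numeric")
)

setValidity("BindingCurve", function(object) {
  if (length(object@concentrationNM) != length(object@counts))
    return("concentrations and counts must have equal length")
  if (any(object@concentrationNM <= 0))
    return("concentrations must be positive (nM)")
  if (is.unsorted(object@concentrationNM, strictly = TRUE))
    return("concentrations must be strictly increasing")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' HillFit: result of a fixed-coefficient (n = 1) Hill fit
#'
#' Two-parameter least-squares fit `counts ~ plateau * c / (kd + c)`.
#' `fractionBound` is `counts / plateau`, clipped to \[0, 1\]; the unclipped
#' normalization is recoverable from `counts` and `plateau`.
#'
#' @slot converged logical(1); FALSE carries a diagnostic in `message`.
#' @slot kdNM numeric(1), dissociation constant (nM); NA on failure.
#' @slot plateau numeric(1), fitted saturation signal; NA on failure.
#' @slot fractionBound numeric, normalized fractions in \[0, 1\].
#' @slot residualSS numeric(1), residual sum of squares of the raw-count fit.
#' @slot message character(1) diagnostic.
#' @export
setClass("HillFit",
  representation(
    converged = "logical",
    kdNM = "numeric",
    plateau = "numeric",
    fractionBound = "numeric",
    residualSS = "numeric",
    message = "character"
  )
)

#' DuplexSequence: an annealed double-stranded DNA
#'
#' @slot nontemplate character(1), the nontemplate strand, 5'->3', over ACGT.
#' @slot template character(1), its exact reverse complement.
#' @slot lengthBp integer(1).
#' @seealso [annealDuplex()], [duplexMW()]
#' @export
setClass("DuplexSequence",
  representation(nontemplate = "character", template = "character",
                 lengthBp = "integer")
)

setValidity("DuplexSequence", function(object) {
  nt <- object@nontemplate
  if (nchar(nt) == 0L) return("duplex must be non-empty")
  if (object@lengthBp != nchar(nt)) return("lengthBp must equal strand length")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  if (!identical(object@template, rc))
    return("template must be the reverse complement of nontemplate")
  TRUE
})

#' AlignmentProfile: per-column symbol counts of a multiple sequence alignment
#'
#' @slot counts integer matrix, symbols (rows, including the gap symbol `-`)
#'   by alignment columns; every column sums to `nSequences`.
#' @slot alphabet character(1), `"protein"` or `"dna"`.
#' @slot nSequences integer(1).
#' @seealso [alignmentProfile()], [entropicConservation()],
#'   [dnaInformationContent()]
#' @export
setClass("AlignmentProfile",
  representation(counts = "matrix", alphabet = "character",
                 nSequences = "integer")
)

setValidity("AlignmentProfile", function(object) {
  if (!object@alphabet %in% c("protein", "dna"))
    return("alphabet must be 'protein' or 'dna'")
  if (is.null(rownames(object@counts)))
    return("counts must have symbol rownames")
  cs <- colSums(object@counts)
  if (length(cs) && any(cs != object@nSequences))
    return("every column's counts must sum to nSequences")
  TRUE
})
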