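# Filter-binding quantification (hyperbolic fit, Hill coefficient fixed at 1)
# and duplex DNA utilities: in-silico annealing and molecular weight.

#' Construct a binding curve
#'
#' @param concentrationNM protein concentrations in nM, strictly increasing
#'   and positive.
#' @param counts raw retained-signal values (non-negative).
#' @return a [BindingCurve]
#' @export
bindingCurve <- function(concentrationNM, counts) {
  new("BindingCurve", concentrationNM = as.numeric(concentrationNM),
      counts = as.numeric(counts))
}

#' Read a two-column binding table
#'
#' Expects a TSV whose first column is the protein concentration with the
#' unit in the header (`nM` or `uM`/`µM`, e.g. `conc_nM`), and whose second
#' column is the raw signal. Concentrations are converted to nM.
#'
#' @param file path to the TSV.
#' @return a [BindingCurve]
#' @export
readBindingTable <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE)
  if (ncol(tab) < 2L) stop("binding table needs two columns")
  hdr <- names(tab)[1]
  scale <- if (grepl("(^|[^a-zA-Z])nM", hdr)) 1 else
    if (grepl("(^|[^a-zA-Z])(uM|µM)", hdr)) 1000 else
      stop("concentration unit (nM or uM) not found in header '", hdr, "'")
  bindingCurve(tab[[1]] * scale, tab[[2]])
}

#' Hyperbolic bound fraction (Hill equation with coefficient 1)
#'
#' `fraction = conc / (kd + conc)`: the single-site binding isotherm, i.e.
#' the Hill equation with the cooperativity coefficient fixed at 1.
#'
#' @param concNM concentration(s) in nM, >= 0.
#' @param kdNM dissociation constant in nM, > 0.
#' @return fraction(s) bound in \[0, 1)
#' @examples
#' hillFraction(20, 20)      # 0.5 at half-saturation
#' hillFraction(9 * 20, 20)  # 0.9
#' @export
hillFraction <- function(concNM, kdNM) {
  if (any(kdNM <= 0)) stop("kdNM must be positive")
  if (any(concNM < 0)) stop("concNM must be non-negative")
  concNM / (kdNM + concNM)
}

.hillFitFailure <- function(curve, msg) {
  new("HillFit", converged = FALSE, kdNM = NA_real_, plateau = NA_real_,
      fractionBound = rep(NA_real_, length(curve@counts)),
      residualSS = NA_real_, message = msg)
}

#' Fit a binding curve to the Hill equation with fixed coefficient 1
#'
#' Two-parameter least squares `counts ~ plateau * conc / (kd + conc)`
#' (Levenberg-Marquardt). Normalization is by the fitted plateau - not by the
#' maximal count, which would be noise-sensitive - and bound fractions are
#' reported relative to it (clipped to \[0, 1\]).
#'
#' The fitted Kd is invariant to rescaling all counts by a positive constant.
#' Data with no overall signal increase (no binding) yield a non-converged
#' [HillFit] with a diagnostic message, not an error.
#'
#' @param curve a [BindingCurve] with at least 4 points spanning at least one
#'   decade of concentration.
#' @return a [HillFit]
#' @export
fitBinding <- function(curve) {
  stopifnot(is(curve, "BindingCurve"))
  conc <- curve@concentrationNM
  y <- curve@counts
  if (length(conc) < 4L)
    stop("need at least 4 concentration points")
  if (max(conc) / min(conc) < 10)
    stop("concentrations must span at least one decade")
  if (all(y == 0))
    return(.hillFitFailure(curve, "all counts are zero - no signal to fit"))
  trend <- stats::cor(log(conc), y)
  if (is.na(trend) || trend <= 0)
    return(.hillFitFailure(curve,
      "signal does not increase with concentration - no binding detected"))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ plateau * conc / (kd + conc),
      start = list(plateau = max(y), kd = stats::median(conc)),
      lower = c(plateau = .Machine$double.eps, kd = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(.hillFitFailure(curve, paste("fit failed:", conditionMessage(fit))))
  cf <- stats::coef(fit)
  frac <- pmin(1, pmax(0, y / cf[["plateau"]]))
  new("HillFit", converged = TRUE, kdNM = cf[["kd"]],
      plateau = cf[["plateau"]], fractionBound = frac,
      residualSS = sum(stats::residuals(fit)^2),
      message = "ok")
}

#' Anneal a nontemplate strand into a duplex
#'
#' Validates the strand (ACGT only, case-insensitive) and generates the
#' template strand as its exact reverse complement.
#'
#' @param nontemplate DNA string, 5'->3'.
#' @return a [DuplexSequence]
#' @examples
#' annealDuplex("AAA")  # template TTT
#' @export
annealDuplex <- function(nontemplate) {
  stopifnot(is.character(nontemplate), length(nontemplate) == 1L)
  nt <- toupper(nontemplate)
  if (nchar(nt) == 0L) stop("sequence must be non-empty")
  chars <- strsplit(nt, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-ACGT character '", chars[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  template <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  new("DuplexSequence", nontemplate = nt, template = template,
      lengthBp = nchar(nt))
}

# anhydrous nucleoside-5'-monophosphate residue masses (Da)
.NMP_RESIDUE_DA <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)

.strandMass <- function(seq) {
  counts <- table(factor(strsplit(seq, "")[[1]],
                         levels = names(.NMP_RESIDUE_DA)))
  sum(as.numeric(counts) * .NMP_RESIDUE_DA)
}

#' Molecular weight of a DNA duplex
#'
#' Default convention: sum of anhydrous nucleoside-5'-monophosphate residue
#' masses (A 313.21, C 289.18, G 329.21, T 304.20 Da) over both strands, with
#' no end-group correction. Alternatives, clearly non-default:
#' `"fiveprimeOH"` subtracts 61.96 Da per strand (5'-OH termini instead of a
#' terminal phosphate); `"perBp650"` is the 650 Da-per-base-pair rule of
#' thumb.
#'
#' @param duplex a [DuplexSequence]
#' @param convention `"residue"` (default), `"fiveprimeOH"` or `"perBp650"`.
#' @return molecular weight in daltons
#' @examples
#' duplexMW(annealDuplex("A"))   # 313.21 + 304.20
#' @export
duplexMW <- function(duplex, convention = c("residue", "fiveprimeOH",
                                            "perBp650")) {
  stopifnot(is(duplex, "DuplexSequence"))
  convention <- match.arg(convention)
  if (convention == "perBp650") return(650 * duplex@lengthBp)
  mw <- .strandMass(duplex@nontemplate) + .strandMass(duplex@template)
  if (convention == "fiveprimeOH") mw <- mw - 2 * 61.96
  mw
}

#' The TRR-TCT3-2 tRNA gene nontemplate strand
#'
#' Returns the 98-nt nontemplate strand of the human TRR-TCT3-2 tRNA gene
#' (the double-stranded substrate of the binding and cryo-EM experiments),
#' read from the FASTA shipped with the package.
#'
#' @return character(1) DNA sequence, uppercase
#' @export
trrTct3Gene <- function() {
  fa <- system.file("extdata", "TRR-TCT3-2_nontemplate.fasta",
                    package = "tetherlink", mustWork = TRUE)
  toupper(as.character(Biostrings::readDNAStringSet(fa)[[1]]))
}
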