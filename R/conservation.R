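# Position-wise conservation: entropy scoring over a reduced amino-acid
# alphabet, per-column DNA information content, and a synthetic-alignment
# generator.

#' Default seven-type amino-acid partition
#'
#' The reduced alphabet used by [entropicConservation()]: aliphatic/small
#' hydrophobic `AVLIMC`, aromatic `FWYH`, polar `STNQ`, basic `KR`, acidic
#' `DE`, and glycine and proline as their own classes (backbone-geometry
#' outliers). This is the package's own convention for a seven-class
#' physicochemical grouping; it is fully overridable via the `partition`
#' argument of the scoring functions.
#'
#' @return named list of 7 character vectors
#' @export
sevenTypePartition <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M", "C"),
       aromatic = c("F", "W", "Y", "H"),
       polar = c("S", "T", "N", "Q"),
       basic = c("K", "R"),
       acidic = c("D", "E"),
       glycine = "G",
       proline = "P")
}

.GAP_CHARS <- c("-", ".")

# Shannon entropy (natural log) of a count vector
.entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Entropic conservation score of an alignment column
#'
#' Maps the column's non-gap residues onto a reduced set of residue type
#' classes (default: seven physicochemical types, [sevenTypePartition()]) and
#' scores `1 - H / log(K)`, where `H` is the Shannon entropy (natural log) of
#' the type frequencies and `K` the number of classes. The score is 1 for an
#' invariant column (all residues in one class) and 0 when the classes are
#' represented uniformly. Gaps are excluded from the frequencies; an all-gap
#' column scores `NA` (undefined, excluded from framing).
#'
#' @param x an [AlignmentProfile] (protein), or a named count vector for a
#'   single column (names: residues, gap `-` allowed).
#' @param partition named list of character vectors assigning each residue to
#'   a type class.
#' @return numeric vector of per-column scores in \[0, 1\] (or a single score)
#' @examples
#' entropicConservation(c(L = 5, V = 5))          # 1: one class
#' entropicConservation(c(A = 5, S = 5))          # 1 - log(2)/log(7)
#' @export
entropicConservation <- function(x, partition = sevenTypePartition()) {
  if (is(x, "AlignmentProfile")) {
    if (x@alphabet != "protein")
      stop("entropic conservation is defined for protein alignments")
    return(apply(x@counts, 2L, .columnConservation, partition = partition))
  }
  .columnConservation(x, partition)
}

.columnConservation <- function(counts, partition) {
  if (is.null(names(counts))) stop("column counts must be named by residue")
  if (any(counts < 0)) stop("counts must be non-negative")
  residues <- toupper(names(counts))
  keep <- !(residues %in% .GAP_CHARS) & counts > 0
  if (!any(keep)) return(NA_real_)
  typeOf <- rep(NA_character_, sum(keep))
  res <- residues[keep]
  for (cls in names(partition))
    typeOf[res %in% toupper(partition[[cls]])] <- cls
  if (anyNA(typeOf))
    stop("residue(s) not covered by the type partition: ",
         paste(unique(res[is.na(typeOf)]), collapse = ", "))
  typeCounts <- tapply(counts[keep], typeOf, sum)
  1 - .entropy(typeCounts) / log(length(partition))
}

#' Per-column information content of a DNA alignment
#'
#' `2 - H2` bits per column, where `H2` is the base-2 Shannon entropy of the
#' column's base frequencies over `{A, C, G, T}` - the height basis of
#' sequence logos (no small-sample correction). Gaps are excluded; a column
#' with no observed base is an error for single-column input and `NA` within
#' a profile.
#'
#' @param x an [AlignmentProfile] (dna), or a named count vector over
#'   `A`, `C`, `G`, `T` for one column.
#' @return information content in bits, in \[0, 2\]
#' @examples
#' dnaInformationContent(c(A = 2, C = 1, G = 1, T = 0))  # 0.5
#' @export
dnaInformationContent <- function(x) {
  if (is(x, "AlignmentProfile")) {
    if (x@alphabet != "dna")
      stop("information content is defined for DNA alignments")
    return(apply(x@counts, 2L, function(cc) {
      cc <- cc[!(toupper(names(cc)) %in% .GAP_CHARS)]
      if (sum(cc) == 0) NA_real_ else .informationContent(cc)
    }))
  }
  counts <- x
  if (is.null(names(counts))) stop("column counts must be named by base")
  counts <- counts[!(toupper(names(counts)) %in% .GAP_CHARS)]
  bad <- setdiff(toupper(names(counts)), c("A", "C", "G", "T"))
  if (length(bad))
    stop("counts must be over {A, C, G, T}; found: ",
         paste(bad, collapse = ", "))
  if (sum(counts) == 0) stop("no observed base in column")
  .informationContent(counts)
}

.informationContent <- function(counts) {
  2 - .entropy(counts) / log(2)
}

#' Positions framed as conserved
#'
#' Returns the 1-based alignment positions whose score strictly exceeds the
#' threshold (default 0.9, the framing convention for highly conserved
#' residues). `NA` scores (all-gap columns) are never framed.
#'
#' @param scores numeric vector of per-column scores.
#' @param threshold framing threshold (strict inequality).
#' @return integer vector of 1-based positions
#' @examples
#' frameConserved(c(0.95, 0.5, 0.91))  # 1 3
#' frameConserved(0.9)                 # empty: strict inequality
#' @export
frameConserved <- function(scores, threshold = 0.9) {
  which(!is.na(scores) & scores > threshold)
}

#' Column count profile of a multiple sequence alignment
#'
#' Tabulates per-column symbol counts (including gaps, symbol `-`; `.` is
#' treated as a gap and folded into `-`) from an aligned set of sequences.
#' Columns where more than half the sequences are gapped are worth treating
#' as low confidence; see `gapFraction()` on the result via
#' `colSums`/[columnCounts()].
#'
#' @param sequences aligned sequences: a character vector, or a
#'   `Biostrings::XStringSet` / `*MultipleAlignment` (all of equal width).
#' @param alphabet `"protein"` or `"dna"`.
#' @return an [AlignmentProfile]
#' @export
alignmentProfile <- function(sequences, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (is(sequences, "MultipleAlignment"))
    sequences <- as.character(sequences)
  if (is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  mat[mat %in% .GAP_CHARS] <- "-"
  syms <- sort(unique(as.vector(mat)))
  counts <- apply(mat, 2L, function(col)
    table(factor(col, levels = syms)))
  counts <- matrix(as.integer(counts), nrow = length(syms),
                   dimnames = list(syms, NULL))
  new("AlignmentProfile", counts = counts, alphabet = alphabet,
      nSequences = length(sequences))
}

#' Read an aligned FASTA into an AlignmentProfile
#'
#' @param file path to an aligned FASTA (gap character `-`).
#' @param alphabet `"protein"` or `"dna"`.
#' @return an [AlignmentProfile]
#' @export
readAlignment <- function(file, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  seqs <- if (alphabet == "protein")
    Biostrings::readAAStringSet(file) else Biostrings::readDNAStringSet(file)
  alignmentProfile(as.character(seqs), alphabet)
}

#' Fraction of gaps per alignment column
#'
#' @param profile an [AlignmentProfile]
#' @return numeric vector in \[0, 1\], one value per column
#' @export
gapFraction <- function(profile) {
  stopifnot(is(profile, "AlignmentProfile"))
  cc <- profile@counts
  gaps <- if ("-" %in% rownames(cc)) cc["-", ] else rep(0L, ncol(cc))
  as.numeric(gaps) / profile@nSequences
}

.ALPHABETS <- list(
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y"),
  dna = c("A", "C", "G", "T")
)

#' Generate a synthetic multiple sequence alignment
#'
#' Seeded generator with per-column ground truth: every sequence copies the
#' consensus, substituting each position with its column's substitution
#' probability (uniform over the other residues of the alphabet) and gapping
#' it with `gapProb`. Columns with substitution probability 0 and no gaps are
#' exactly invariant.
#'
#' @param nSequences number of sequences.
#' @param length alignment width; ignored when `consensus` is given.
#' @param consensus optional consensus string; default: random residues.
#' @param subProb substitution probability, scalar or per-column vector.
#' @param gapProb per-position gap probability, scalar or per-column vector.
#' @param alphabet `"protein"` or `"dna"`.
#' @param seed integer seed.
#' @return list with `sequences` (named character vector, FASTA-ready),
#'   `consensus`, `subProb` and `gapProb` (per-column ground truth)
#' @export
generateMsa <- function(nSequences, length = NULL, consensus = NULL,
                        subProb = 0.05, gapProb = 0,
                        alphabet = c("protein", "dna"), seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(nSequences >= 1L)
  if (any(subProb < 0 | subProb > 1) || any(gapProb < 0 | gapProb > 1))
    stop("probabilities must lie in [0, 1]")
  letters <- .ALPHABETS[[alphabet]]
  set.seed(seed)
  if (is.null(consensus)) {
    stopifnot(!is.null(length), length >= 1L)
    cons <- sample(letters, length, replace = TRUE)
  } else {
    cons <- strsplit(toupper(consensus), "")[[1]]
    if (!all(cons %in% letters))
      stop("consensus contains symbols outside the ", alphabet, " alphabet")
  }
  L <- base::length(cons)
  subProb <- rep_len(subProb, L)
  gapProb <- rep_len(gapProb, L)
  seqs <- vapply(seq_len(nSequences), function(s) {
    chars <- cons
    sub <- stats::runif(L) < subProb
    if (any(sub)) {
      chars[sub] <- vapply(which(sub), function(j)
        sample(setdiff(letters, cons[j]), 1L), character(1))
    }
    gap <- stats::runif(L) < gapProb
    chars[gap] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("seq_%04d", seq_len(nSequences))
  list(sequences = seqs, consensus = paste(cons, collapse = ""),
       subProb = subProb, gapProb = gapProb)
}

#' Write per-column conservation scores as TSV
#'
#' @param scores numeric per-column scores (protein) or bits (dna).
#' @param file output path.
#' @param lowConfidence optional logical vector flagging columns (e.g. > 50%
#'   gaps).
#' @return invisibly, the file path
#' @export
writeConservationTable <- function(scores, file, lowConfidence = NULL) {
  flag <- if (is.null(lowConfidence)) rep(FALSE, length(scores)) else
    lowConfidence
  utils::write.table(
    data.frame(position = seq_along(scores),
               score = ifelse(is.na(scores), "NA", sprintf("%.6f", scores)),
               low_confidence = flag),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
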