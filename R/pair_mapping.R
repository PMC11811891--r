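# Greedy per-micrograph pairing of two particle populations and the
# randomized-coordinate null.

#' Euclidean distance matrix between two particle populations
#'
#' @param coordsB,coordsA two-column numeric matrices (or data.frames) of
#'   positions in Angstrom; rows of the result index `coordsB`, columns index
#'   `coordsA`. Either may have zero rows.
#' @return numeric matrix of size `nrow(coordsB) x nrow(coordsA)` with
#'   non-negative finite entries.
#' @examples
#' buildDistanceMatrix(cbind(0, 0), cbind(3, 4))  # 5
#' @export
buildDistanceMatrix <- function(coordsB, coordsA) {
  coordsB <- as.matrix(coordsB)
  coordsA <- as.matrix(coordsA)
  if (ncol(coordsB) != 2L && nrow(coordsB) > 0L)
    stop("coordsB must have two columns (x, y)")
  if (ncol(coordsA) != 2L && nrow(coordsA) > 0L)
    stop("coordsA must have two columns (x, y)")
  if (nrow(coordsB) == 0L || nrow(coordsA) == 0L)
    return(matrix(numeric(0), nrow = nrow(coordsB), ncol = nrow(coordsA)))
  if (any(!is.finite(coordsB)) || any(!is.finite(coordsA)))
    stop("coordinates must be finite")
  dx <- outer(coordsB[, 1], coordsA[, 1], `-`)
  dy <- outer(coordsB[, 2], coordsA[, 2], `-`)
  sqrt(dx * dx + dy * dy)
}

#' Greedy delete-minimum pairing of a distance matrix
#'
#' Repeatedly selects the globally smallest entry of the matrix, records the
#' pair, and removes its row and column, until the rows or the columns are
#' exhausted. Each particle is therefore used at most once, and the recorded
#' distances are nondecreasing in selection order. Exact ties are broken by
#' the smallest row index, then the smallest column index.
#'
#' This is the greedy successive-minimum rule, not the optimal (minimum total
#' cost) bipartite assignment: on `rbind(c(1, 2), c(5, 8))` it selects
#' distances 1 and 8, whereas the optimal assignment would pick 2 and 5.
#'
#' @param m numeric matrix of non-negative finite distances.
#' @return data.frame with columns `rowIdx`, `colIdx`, `distance`, one row per
#'   selected pair, in selection order; `min(nrow(m), ncol(m))` rows in total.
#' @examples
#' greedyPair(rbind(c(1, 2), c(5, 8)))
#' @export
greedyPair <- function(m) {
  m <- as.matrix(m)
  if (length(m) && (any(!is.finite(m)) || any(m < 0)))
    stop("distance matrix entries must be finite and non-negative")
  nPairs <- min(nrow(m), ncol(m))
  rowIdx <- integer(nPairs)
  colIdx <- integer(nPairs)
  dist <- numeric(nPairs)
  if (nPairs > 0L) {
    work <- m
    for (k in seq_len(nPairs)) {
      mv <- min(work)
      hits <- which(work == mv, arr.ind = TRUE)
      # ties: smallest row index, then smallest column index
      hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
      i <- hits[1L, 1L]; j <- hits[1L, 2L]
      rowIdx[k] <- i; colIdx[k] <- j; dist[k] <- mv
      work[i, ] <- Inf
      work[, j] <- Inf
    }
  }
  data.frame(rowIdx = rowIdx, colIdx = colIdx, distance = dist)
}

#' Pair two particle populations micrograph by micrograph
#'
#' For every micrograph present in both tables, builds the distance matrix of
#' refined positions (rows: `tableB`, columns: `tableA`) and applies
#' [greedyPair()]; pair lists are pooled across micrographs (micrographs in
#' sorted order, selection order within each). Micrographs present in only one
#' table contribute no pairs and are recorded as skipped.
#'
#' @param tableB,tableA two [ParticleSet]s sharing micrograph identifiers.
#'   By convention `tableB` supplies the matrix rows.
#' @return a [PairingResult]
#' @export
pairAllMicrographs <- function(tableB, tableA) {
  stopifnot(is(tableB, "ParticleSet"), is(tableA, "ParticleSet"))
  posB <- refinedPositions(tableB)
  posA <- refinedPositions(tableA)
  micsB <- unique(posB$micrograph)
  micsA <- unique(posA$micrograph)
  shared <- sort(intersect(micsB, micsA))
  skipped <- sort(c(setdiff(micsB, micsA), setdiff(micsA, micsB)))
  if (length(shared) == 0L) {
    warning("the two particle tables share no micrograph; 0 pairs produced")
    return(new("PairingResult",
               pairs = data.frame(micrograph = character(0),
                                  rowIdx = integer(0), colIdx = integer(0),
                                  distance = numeric(0)),
               skippedMicrographs = skipped,
               nSharedMicrographs = 0L))
  }
  splitB <- split(seq_len(nrow(posB)), posB$micrograph)
  splitA <- split(seq_len(nrow(posA)), posA$micrograph)
  res <- lapply(shared, function(mic) {
    ib <- splitB[[mic]]
    ia <- splitA[[mic]]
    dm <- buildDistanceMatrix(cbind(posB$xA[ib], posB$yA[ib]),
                              cbind(posA$xA[ia], posA$yA[ia]))
    g <- greedyPair(dm)
    if (nrow(g)) g$micrograph <- mic
    g
  })
  res <- res[vapply(res, nrow, integer(1)) > 0L]
  pairs <- if (length(res)) {
    out <- do.call(rbind, res)
    out[, c("micrograph", "rowIdx", "colIdx", "distance")]
  } else {
    data.frame(micrograph = character(0), rowIdx = integer(0),
               colIdx = integer(0), distance = numeric(0))
  }
  rownames(pairs) <- NULL
  new("PairingResult", pairs = pairs, skippedMicrographs = skipped,
      nSharedMicrographs = length(shared))
}

#' Randomize particle coordinates within each micrograph
#'
#' Replaces every particle's position by an independent uniform draw on
#' `[0, fieldWA) x [0, fieldHA)`, keeping the per-micrograph particle counts.
#' This is the null model for the pairing analysis: the same particle sets,
#' with spatial structure destroyed. Deterministic given `seed`; each
#' micrograph uses its own substream (keyed by its rank in sorted name order),
#' so a micrograph's null coordinates do not depend on which other micrographs
#' are present.
#'
#' When field extents are omitted they default, per axis and per micrograph,
#' to the maximum observed refined coordinate, with a warning: data-derived
#' extents bias the null slightly inward.
#'
#' @param table a [ParticleSet]
#' @param fieldWA,fieldHA field extent in Angstrom (positive), or `NULL` for
#'   data-derived extents.
#' @param seed integer seed.
#' @return a [ParticleSet] with randomized coordinates (origin shifts 0)
#' @export
randomizeCoordinates <- function(table, fieldWA = NULL, fieldHA = NULL,
                                 seed = 1L) {
  stopifnot(is(table, "ParticleSet"))
  if (!is.null(fieldWA) && fieldWA <= 0) stop("fieldWA must be positive")
  if (!is.null(fieldHA) && fieldHA <= 0) stop("fieldHA must be positive")
  derived <- is.null(fieldWA) || is.null(fieldHA)
  if (derived)
    warning("field extent(s) not given; deriving from the data ",
            "(max observed coordinate per axis, per micrograph) - ",
            "this biases the null slightly inward")
  pos <- refinedPositions(table)
  p <- table@particles
  mics <- sort(unique(p$micrograph))
  for (k in seq_along(mics)) {
    idx <- which(p$micrograph == mics[k])
    w <- if (is.null(fieldWA)) max(pos$xA[idx]) else fieldWA
    h <- if (is.null(fieldHA)) max(pos$yA[idx]) else fieldHA
    if (w <= 0 || h <= 0)
      stop("derived field extent is non-positive for micrograph ", mics[k])
    set.seed(.substreamSeed(seed, k))
    n <- length(idx)
    p$xPx[idx] <- runif(n, 0, w) / table@pixelSize
    p$yPx[idx] <- runif(n, 0, h) / table@pixelSize
    p$originXA[idx] <- 0
    p$originYA[idx] <- 0
  }
  new("ParticleSet", particles = p, pixelSize = table@pixelSize,
      population = paste0(table@population, "_null"))
}

#' Pooled null pairing distances over randomized replicates
#'
#' Runs [randomizeCoordinates()] on both tables with replicate-specific
#' substream seeds and pools each replicate's greedy pairing distances.
#'
#' @param tableB,tableA the observed [ParticleSet]s.
#' @param fieldWA,fieldHA null field extents in Angstrom (see
#'   [randomizeCoordinates()]).
#' @param replicates number of independent randomizations (default 10).
#' @param seed integer master seed.
#' @return list of numeric vectors, one pooled distance vector per replicate
#' @export
nullPairingDistances <- function(tableB, tableA, fieldWA = NULL,
                                 fieldHA = NULL, replicates = 10L,
                                 seed = 1L) {
  stopifnot(replicates >= 1L)
  lapply(seq_len(replicates), function(r) {
    nb <- randomizeCoordinates(tableB, fieldWA, fieldHA,
                               seed = .substreamSeed(seed, 2L * r))
    na <- randomizeCoordinates(tableA, fieldWA, fieldHA,
                               seed = .substreamSeed(seed, 2L * r + 1L))
    suppressWarnings(pairDistances(pairAllMicrographs(nb, na)))
  })
}

# deterministic 31-bit substream seed; exact in double arithmetic
.substreamSeed <- function(seed, k) {
  v <- (as.double(seed) %% 2147483647) * 48271 + 100003 * as.double(k)
  as.integer(v %% 2147483647)
}
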