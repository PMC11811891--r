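# RELION-style STAR particle table input/output.
#
# Only the subset of the STAR grammar produced by single-particle refinement
# is supported: named data blocks, each either a loop_ table or bare
# tag/value lines. Multi-line strings and quoting are not handled.

.STAR_TAGS <- list(
  micrograph = "_rlnMicrographName",
  x = "_rlnCoordinateX",
  y = "_rlnCoordinateY",
  originXA = "_rlnOriginXAngst",
  originYA = "_rlnOriginYAngst",
  originXPx = "_rlnOriginX",
  originYPx = "_rlnOriginY",
  pixelSize = "_rlnImagePixelSize"
)

# Parse STAR text into a list of blocks; each block is a list(tags, rows)
# for loop_ blocks or list(pairs) for tag/value blocks.
.parseStarBlocks <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (startsWith(lines[i], "data_")) {
      name <- substring(lines[i], 6L)
      i <- i + 1L
      # skip blanks
      while (i <= n && lines[i] == "") i <- i + 1L
      if (i <= n && lines[i] == "loop_") {
        i <- i + 1L
        tags <- character(0)
        while (i <= n && startsWith(lines[i], "_")) {
          tags <- c(tags, strsplit(lines[i], "[ \t]+")[[1]][1])
          i <- i + 1L
        }
        rows <- list()
        while (i <= n && lines[i] != "" && !startsWith(lines[i], "data_")) {
          rows[[length(rows) + 1L]] <- strsplit(lines[i], "[ \t]+")[[1]]
          i <- i + 1L
        }
        blocks[[length(blocks) + 1L]] <-
          list(name = name, tags = tags, rows = rows)
      } else {
        pairs <- list()
        while (i <= n && !startsWith(lines[i], "data_")) {
          if (startsWith(lines[i], "_")) {
            kv <- strsplit(lines[i], "[ \t]+")[[1]]
            pairs[[kv[1]]] <- kv[2]
          }
          i <- i + 1L
        }
        blocks[[length(blocks) + 1L]] <- list(name = name, pairs = pairs)
      }
    } else {
      i <- i + 1L
    }
  }
  blocks
}

.starColumn <- function(block, tag) {
  j <- match(tag, block$tags)
  if (is.na(j)) return(NULL)
  vapply(block$rows, function(r) {
    if (length(r) < j) NA_character_ else r[j]
  }, character(1))
}

.numericColumn <- function(vals, tag) {
  out <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(out) & !is.na(vals))
  if (length(bad))
    stop("non-numeric value in column ", tag, " at row ", bad[1],
         " ('", vals[bad[1]], "')", call. = FALSE)
  out
}

# pixel size declared inside the STAR file (optics block or any block that
# carries _rlnImagePixelSize), or NA when absent
.starPixelSize <- function(blocks) {
  vals <- numeric(0)
  for (b in blocks) {
    if (!is.null(b$tags)) {
      v <- .starColumn(b, .STAR_TAGS$pixelSize)
      if (!is.null(v)) vals <- c(vals, .numericColumn(v, .STAR_TAGS$pixelSize))
    } else if (!is.null(b$pairs[[.STAR_TAGS$pixelSize]])) {
      vals <- c(vals, as.numeric(b$pairs[[.STAR_TAGS$pixelSize]]))
    }
  }
  vals <- unique(vals)
  if (length(vals) == 0L) return(NA_real_)
  if (length(vals) > 1L)
    stop("conflicting pixel sizes declared in STAR file: ",
         paste(format(vals), collapse = ", "), call. = FALSE)
  vals
}

#' Read a RELION-style particle STAR table
#'
#' Parses the particle table of a refinement STAR file into a [ParticleSet].
#' The block holding the particles is located by its coordinate tags
#' (`_rlnCoordinateX/Y` plus `_rlnMicrographName`); origin shifts
#' (`_rlnOriginXAngst/_rlnOriginYAngst`, Angstrom) are optional and default
#' to 0. Legacy pixel-unit origin columns (`_rlnOriginX/Y`) are converted to
#' Angstrom by multiplying with the pixel size.
#'
#' The pixel size is taken from the file (an optics block, when present) or
#' from `pixelSizeA`; if both are given they must agree, otherwise an error
#' is raised rather than silently preferring one.
#'
#' @param file path to a STAR file, or `NULL` when `text` is given.
#' @param pixelSizeA Angstrom per pixel; may be omitted when the file declares
#'   `_rlnImagePixelSize`.
#' @param population label for the particle population (e.g. `"tauA"`).
#' @param text STAR content as a character scalar or vector of lines
#'   (alternative to `file`).
#' @param basenameOnly strip directory components from micrograph names, so
#'   tables refined in different working directories still share micrograph
#'   identifiers. Default `FALSE`: names are matched verbatim.
#' @return a [ParticleSet]
#' @examples
#' star <- c("data_particles", "loop_",
#'   "_rlnMicrographName #1", "_rlnCoordinateX #2", "_rlnCoordinateY #3",
#'   "mic1.mrc 100 200", "mic1.mrc 300 400")
#' readParticles(text = star, pixelSizeA = 0.822, population = "tauA")
#' @export
readParticles <- function(file = NULL, pixelSizeA = NULL,
                          population = "particles", text = NULL,
                          basenameOnly = FALSE) {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  blocks <- .parseStarBlocks(lines)
  if (length(blocks) == 0L)
    stop("no data block found in STAR input", call. = FALSE)

  loops <- Filter(function(b) !is.null(b$tags), blocks)
  isParticle <- vapply(loops, function(b)
    all(c(.STAR_TAGS$x, .STAR_TAGS$micrograph) %in% b$tags) ||
      any(c(.STAR_TAGS$x, .STAR_TAGS$y) %in% b$tags), logical(1))
  if (!any(isParticle))
    stop("no particle block with coordinate columns found", call. = FALSE)
  pb <- loops[isParticle][[1]]

  for (tag in c(.STAR_TAGS$micrograph, .STAR_TAGS$x, .STAR_TAGS$y)) {
    if (!tag %in% pb$tags)
      stop("required column ", tag, " missing from particle block",
           call. = FALSE)
  }

  filePx <- .starPixelSize(blocks)
  if (!is.na(filePx) && !is.null(pixelSizeA)) {
    if (abs(filePx - pixelSizeA) > 1e-9)
      stop("pixel size conflict: file declares ", format(filePx),
           " A/px but ", format(pixelSizeA), " A/px was supplied",
           call. = FALSE)
  }
  px <- if (!is.na(filePx)) filePx else pixelSizeA
  if (is.null(px) || is.na(px))
    stop("pixel size is required (not declared in file, not supplied)",
         call. = FALSE)
  if (px <= 0) stop("pixel size must be positive", call. = FALSE)

  mic <- .starColumn(pb, .STAR_TAGS$micrograph)
  if (basenameOnly) mic <- basename(mic)
  xPx <- .numericColumn(.starColumn(pb, .STAR_TAGS$x), .STAR_TAGS$x)
  yPx <- .numericColumn(.starColumn(pb, .STAR_TAGS$y), .STAR_TAGS$y)
  nr <- length(mic)

  getOrigin <- function(tagA, tagPx) {
    v <- .starColumn(pb, tagA)
    if (!is.null(v)) return(.numericColumn(v, tagA))
    v <- .starColumn(pb, tagPx)
    if (!is.null(v)) return(.numericColumn(v, tagPx) * px)
    rep(0, nr)
  }
  oxA <- getOrigin(.STAR_TAGS$originXA, .STAR_TAGS$originXPx)
  oyA <- getOrigin(.STAR_TAGS$originYA, .STAR_TAGS$originYPx)

  new("ParticleSet",
      particles = data.frame(micrograph = mic, xPx = xPx, yPx = yPx,
                             originXA = oxA, originYA = oyA,
                             stringsAsFactors = FALSE),
      pixelSize = px, population = population)
}

#' Refined particle positions in Angstrom
#'
#' Converts picked pixel coordinates plus refinement origin shifts to refined
#' physical positions: `x_A = xPx * pixelSize - originX_A` (likewise y).
#'
#' @param x a [ParticleSet]
#' @return data.frame with columns `micrograph`, `xA`, `yA`
#' @export
setGeneric("refinedPositions", function(x) standardGeneric("refinedPositions"))

#' @export
setMethod("refinedPositions", "ParticleSet", function(x) {
  p <- x@particles
  data.frame(micrograph = p$micrograph,
             xA = p$xPx * x@pixelSize - p$originXA,
             yA = p$yPx * x@pixelSize - p$originYA,
             stringsAsFactors = FALSE)
})

#' Write a ParticleSet as STAR text
#'
#' Emits an optics block carrying the pixel size and a particle block with
#' micrograph name, picked pixel coordinates and Angstrom origin shifts.
#' `readParticles()` applied to the output reproduces the input table
#' (coordinates within 1e-6 Angstrom). Output is deterministic: identical
#' tables yield byte-identical text.
#'
#' @param x a [ParticleSet]
#' @param file optional path; when `NULL` the STAR text is returned as a
#'   character vector of lines.
#' @return invisibly (file written) or the text lines
#' @export
setGeneric("writeParticles", function(x, file = NULL)
  standardGeneric("writeParticles"))

#' @export
setMethod("writeParticles", "ParticleSet", function(x, file = NULL) {
  p <- x@particles
  num <- function(v) sprintf("%.6f", v)
  header <- c(
    "# version 30001",
    "",
    "data_optics",
    "",
    "loop_",
    "_rlnOpticsGroup #1",
    paste0(.STAR_TAGS$pixelSize, " #2"),
    paste("1", num(x@pixelSize)),
    "",
    "data_particles",
    "",
    "loop_",
    paste0(.STAR_TAGS$micrograph, " #1"),
    paste0(.STAR_TAGS$x, " #2"),
    paste0(.STAR_TAGS$y, " #3"),
    paste0(.STAR_TAGS$originXA, " #4"),
    paste0(.STAR_TAGS$originYA, " #5")
  )
  rows <- if (nrow(p) == 0L) character(0) else
    paste(p$micrograph, num(p$xPx), num(p$yPx), num(p$originXA),
          num(p$originYA))
  out <- c(header, rows, "")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
})
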