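# Independent brute-force oracle for the delete-minimum pairing rule: literally
# materializes the matrix, scans every remaining entry with nested loops, and
# shrinks the index sets. Kept deliberately naive and separate from the
# package's implementation.
bruteGreedy <- function(m) {
  rows <- seq_len(nrow(m))
  cols <- seq_len(ncol(m))
  rowIdx <- integer(0); colIdx <- integer(0); dist <- numeric(0)
  while (length(rows) && length(cols)) {
    bi <- NA_integer_; bj <- NA_integer_; bv <- Inf
    for (i in seq_along(rows)) {
      for (j in seq_along(cols)) {
        v <- m[rows[i], cols[j]]
        if (v < bv) { bv <- v; bi <- i; bj <- j }
      }
    }
    rowIdx <- c(rowIdx, rows[bi])
    colIdx <- c(colIdx, cols[bj])
    dist <- c(dist, bv)
    rows <- rows[-bi]
    cols <- cols[-bj]
  }
  data.frame(rowIdx = rowIdx, colIdx = colIdx, distance = dist)
}

# random micrograph point sets for property tests
randomScene <- function(nB, nA, w = 1000, h = 800) {
  list(B = cbind(runif(nB, 0, w), runif(nB, 0, h)),
       A = cbind(runif(nA, 0, w), runif(nA, 0, h)))
}

# small STAR fixture used across the star-io tests
starFixture <- function(rows,
                        tags = c("_rlnMicrographName", "_rlnCoordinateX",
                                 "_rlnCoordinateY")) {
  c("data_particles", "", "loop_",
    paste0(tags, " #", seq_along(tags)), rows)
}
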