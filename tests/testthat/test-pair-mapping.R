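test_that("distance matrix holds pairwise Euclidean distances", {
  expect_equal(buildDistanceMatrix(cbind(0, 0), cbind(3, 4)),
               matrix(5, 1, 1))
  expect_equal(buildDistanceMatrix(rbind(c(0, 0), c(1, 0)), cbind(0, 0)),
               matrix(c(0, 1), 2, 1))
  expect_equal(buildDistanceMatrix(rbind(c(1, 0), c(-5, 0)),
                                   rbind(c(0, 0), c(3, 0))),
               rbind(c(1, 2), c(5, 8)))
  # empty inputs give zero-extent matrices, not errors
  expect_equal(dim(buildDistanceMatrix(matrix(numeric(0), 0, 2),
                                       cbind(1, 2))), c(0L, 1L))
})

test_that("greedy pairing follows the delete-minimum rule, not optimality", {
  expect_equal(greedyPair(matrix(5, 1, 1)),
               data.frame(rowIdx = 1L, colIdx = 1L, distance = 5))
  # globally-min-sum assignment would be {2, 5}; the greedy rule picks 1, 8
  g <- greedyPair(rbind(c(1, 2), c(5, 8)))
  expect_equal(g$distance, c(1, 8))
  expect_equal(g$rowIdx, c(1L, 2L))
  # ties: smallest row index, then smallest column index
  tie <- greedyPair(rbind(c(1, 1), c(2, 3)))
  expect_equal(tie$rowIdx, c(1L, 2L))
  expect_equal(tie$colIdx, c(1L, 2L))
  expect_equal(tie$distance, c(1, 3))
  # zero-extent matrix
  expect_equal(nrow(greedyPair(matrix(numeric(0), 0, 3))), 0L)
})

test_that("greedy pairing matches the brute-force delete-min oracle", {
  set.seed(101)
  for (trial in 1:60) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    m <- matrix(runif(nr * nc, 0, 100), nr, nc)
    expect_equal(greedyPair(m), bruteGreedy(m))
  }
  # with deliberate ties
  set.seed(102)
  for (trial in 1:20) {
    m <- matrix(sample(1:4, 25, replace = TRUE), 5, 5)
    expect_equal(greedyPair(m), bruteGreedy(m))
  }
})

test_that("pairing invariants hold on random scenes", {
  set.seed(7)
  for (trial in 1:50) {
    sc <- randomScene(sample(0:8, 1), sample(0:8, 1))
    g <- greedyPair(buildDistanceMatrix(sc$B, sc$A))
    expect_equal(nrow(g), min(nrow(sc$B), nrow(sc$A)))
    expect_equal(anyDuplicated(g$rowIdx), 0L)
    expect_equal(anyDuplicated(g$colIdx), 0L)
    expect_true(all(diff(g$distance) >= 0))
  }
})

test_that("pairing is equivariant under row/column permutations", {
  set.seed(55)
  for (trial in 1:20) {
    m <- matrix(runif(30), 5, 6)  # distinct entries a.s.
    pr <- sample(5); pc <- sample(6)
    g0 <- greedyPair(m)
    g1 <- greedyPair(m[pr, pc])
    expect_equal(sort(g0$distance), sort(g1$distance))
    # mapping permuted indices back gives the same pair set
    expect_setequal(paste(g0$rowIdx, g0$colIdx),
                    paste(pr[g1$rowIdx], pc[g1$colIdx]))
  }
})

test_that("micrographs are paired independently and pooled", {
  mk <- function(df, pop) new("ParticleSet", particles = df, pixelSize = 1,
                              population = pop)
  b <- mk(data.frame(micrograph = "m1", xPx = 0, yPx = 0,
                     originXA = 0, originYA = 0), "tauB")
  a <- mk(data.frame(micrograph = "m1", xPx = 7, yPx = 0,
                     originXA = 0, originYA = 0), "tauA")
  pr <- pairAllMicrographs(b, a)
  expect_equal(pairDistances(pr), 7)

  # two micrographs: per-micrograph results pooled by concatenation
  b2 <- mk(data.frame(micrograph = c("m1", "m1", "m2"),
                      xPx = c(0, 10, 0), yPx = 0,
                      originXA = 0, originYA = 0), "tauB")
  a2 <- mk(data.frame(micrograph = c("m1", "m1", "m2"),
                      xPx = c(1, 18, 7), yPx = 0,
                      originXA = 0, originYA = 0), "tauA")
  pr2 <- pairAllMicrographs(b2, a2)
  expect_equal(length(pairDistances(pr2)), 3L)
  expect_equal(pairTable(pr2)$distance, c(1, 8, 7))

  # disjoint micrographs: zero pairs, both skipped, warning not error
  bD <- mk(data.frame(micrograph = "m2", xPx = 0, yPx = 0,
                      originXA = 0, originYA = 0), "tauB")
  aD <- mk(data.frame(micrograph = "m1", xPx = 0, yPx = 0,
                      originXA = 0, originYA = 0), "tauA")
  expect_warning(prD <- pairAllMicrographs(bD, aD), "share no micrograph")
  expect_equal(length(pairDistances(prD)), 0L)
  expect_equal(length(skippedMicrographs(prD)), 2L)
})

test_that("coordinate randomization preserves counts and is seeded", {
  sc <- simulateScene(sceneParams(nMicrographs = 2L, seed = 9L))
  r1 <- randomizeCoordinates(sc$tableA, 11210, 7965, seed = 4L)
  r2 <- randomizeCoordinates(sc$tableA, 11210, 7965, seed = 4L)
  expect_equal(particleData(r1), particleData(r2))
  expect_equal(table(particleData(r1)$micrograph),
               table(particleData(sc$tableA)$micrograph))
  pos <- refinedPositions(r1)
  expect_true(all(pos$xA >= 0 & pos$xA < 11210))
  expect_true(all(pos$yA >= 0 & pos$yA < 7965))
  r3 <- randomizeCoordinates(sc$tableA, 11210, 7965, seed = 5L)
  expect_false(identical(particleData(r1)$xPx, particleData(r3)$xPx))

  expect_error(randomizeCoordinates(sc$tableA, -1, 10, seed = 1L),
               "positive")
  expect_warning(randomizeCoordinates(sc$tableA, seed = 1L),
                 "deriving from the data")
})

test_that("two independent null randomizations are KS-indistinguishable", {
  sc <- simulateScene(sceneParams(nMicrographs = 20L, seed = 31L))
  d1 <- unlist(nullPairingDistances(sc$tableB, sc$tableA, 11210, 7965,
                                    replicates = 1L, seed = 100L))
  d2 <- unlist(nullPairingDistances(sc$tableB, sc$tableA, 11210, 7965,
                                    replicates = 1L, seed = 200L))
  ks <- unname(suppressWarnings(stats::ks.test(d1, d2)$statistic))
  expect_lt(ks, ksCriticalValue(length(d1), length(d2), alpha = 0.01))
})
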