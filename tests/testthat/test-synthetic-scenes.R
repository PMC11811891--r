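test_that("scene parameter bounds are enforced", {
  expect_error(sceneParams(fieldWA = -1), "positive")
  expect_error(sceneParams(nMicrographs = 0L), ">= 1")
  expect_error(sceneParams(detectProbA = 1.2), "\\[0, 1\\]")
  expect_error(sceneParams(tetherSigmaA = -5), ">= 0")
  expect_s4_class(sceneParams(), "SceneParams")
})

test_that("projected tether separations follow the Rayleigh law", {
  # degenerate tether: exact zeros
  expect_equal(sampleProjectedSeparation(5, 0), rep(0, 5))
  expect_error(sampleProjectedSeparation(5, -1), ">= 0")

  d <- sampleProjectedSeparation(20000, 200, seed = 2)
  # Rayleigh mean = sigma * sqrt(pi/2) ~ 250.66
  expect_lt(abs(mean(d) / (200 * sqrt(pi / 2)) - 1), 0.01)
  # empirical mode (20 A bins) at the scale parameter
  m <- modeEstimate(distanceHistogram(d, binWidth = 20))
  expect_gte(m, 180)
  expect_lte(m, 220)
})

test_that("degenerate scenes place pairs exactly as specified", {
  p <- sceneParams(nMicrographs = 1L, pairsPerMicrograph = 1L,
                   tetherSigmaA = 0, freeAPerMicrograph = 0L,
                   freeBPerMicrograph = 0L, detectProbA = 1,
                   detectProbB = 1, seed = 3L)
  sc <- simulateScene(p)
  expect_equal(nParticles(sc$tableA), 1L)
  expect_equal(nParticles(sc$tableB), 1L)
  pr <- pairAllMicrographs(sc$tableB, sc$tableA)
  expect_equal(pairDistances(pr), 0)
  expect_equal(sc$truth$trueDistanceA, 0)

  # extinct A detection: only free-A particles remain
  pExt <- sceneParams(nMicrographs = 4L, pairsPerMicrograph = 5L,
                      freeAPerMicrograph = 3L, detectProbA = 0, seed = 8L)
  scExt <- simulateScene(pExt)
  expect_equal(nParticles(scExt$tableA), 4L * 3L)
  expect_equal(nrow(scExt$truth), 0L)
})

test_that("generated coordinates stay inside the field", {
  sc <- simulateScene(sceneParams(nMicrographs = 5L, seed = 23L))
  for (tb in list(sc$tableA, sc$tableB)) {
    pos <- refinedPositions(tb)
    expect_true(all(pos$xA >= 0 & pos$xA < 11210))
    expect_true(all(pos$yA >= 0 & pos$yA < 7965))
  }
})

test_that("retained genuine-pair count matches binomial moments", {
  p <- sceneParams(nMicrographs = 50L, pairsPerMicrograph = 20L,
                   detectProbA = 0.8, detectProbB = 0.9, seed = 13L)
  sc <- simulateScene(p)
  expected <- 50 * 20 * 0.8 * 0.9  # 720
  sdev <- sqrt(50 * 20 * 0.72 * (1 - 0.72))
  expect_lt(abs(nrow(sc$truth) - expected), 4 * sdev)
})

test_that("truth ledger indices point at the genuine partners", {
  p <- sceneParams(nMicrographs = 3L, pairsPerMicrograph = 4L,
                   tetherSigmaA = 150, freeAPerMicrograph = 2L,
                   freeBPerMicrograph = 2L, seed = 77L)
  sc <- simulateScene(p)
  posA <- refinedPositions(sc$tableA)
  posB <- refinedPositions(sc$tableB)
  for (k in seq_len(nrow(sc$truth))) {
    mic <- sc$truth$micrograph[k]
    ia <- which(posA$micrograph == mic)[sc$truth$aIndex[k]]
    ib <- which(posB$micrograph == mic)[sc$truth$bIndex[k]]
    d <- sqrt((posA$xA[ia] - posB$xA[ib])^2 + (posA$yA[ia] - posB$yA[ib])^2)
    expect_equal(d, sc$truth$trueDistanceA[k], tolerance = 1e-9)
  }
})

test_that("scenes are reproducible and stable under micrograph-count changes", {
  p5 <- sceneParams(nMicrographs = 5L, seed = 42L)
  s1 <- simulateScene(p5)
  s2 <- simulateScene(p5)
  expect_equal(particleData(s1$tableA), particleData(s2$tableA))
  expect_equal(s1$truth, s2$truth)
  # per-micrograph substreams: first micrographs unchanged when more are added
  p8 <- sceneParams(nMicrographs = 8L, seed = 42L)
  s3 <- simulateScene(p8)
  keep <- particleData(s3$tableA)$micrograph %in%
    particleData(s1$tableA)$micrograph
  expect_equal(particleData(s3$tableA)[keep, ], particleData(s1$tableA))
})

test_that("oversized tethers warn instead of failing", {
  p <- sceneParams(fieldWA = 300, fieldHA = 300, nMicrographs = 1L,
                   pairsPerMicrograph = 2L, tetherSigmaA = 200,
                   freeAPerMicrograph = 0L, freeBPerMicrograph = 0L,
                   seed = 1L)
  expect_warning(simulateScene(p), "truncated")
})

test_that("export round-trips through STAR and is byte-deterministic", {
  sc <- simulateScene(sceneParams(nMicrographs = 2L, seed = 6L))
  dir <- withr::local_tempdir()
  fA <- file.path(dir, "A.star"); fB <- file.path(dir, "B.star")
  fT <- file.path(dir, "truth.tsv")
  exportScene(sc, fA, fB, truthFile = fT)
  backA <- readParticles(fA, population = "tauA")
  posOrig <- refinedPositions(sc$tableA)
  posBack <- refinedPositions(backA)
  expect_lt(max(abs(posOrig$xA - posBack$xA),
                abs(posOrig$yA - posBack$yA)), 1e-3)
  expect_equal(pixelSize(backA), 0.822)

  # repeated export of the same seeded scene: byte-identical files
  fA2 <- file.path(dir, "A2.star")
  fB2 <- file.path(dir, "B2.star")
  exportScene(simulateScene(sceneParams(nMicrographs = 2L, seed = 6L)),
              fA2, fB2)
  expect_identical(readLines(fA), readLines(fA2))
  expect_identical(readLines(fB), readLines(fB2))

  truth <- read.delim(fT)
  expect_equal(nrow(truth), nrow(sc$truth))

  # empty scene exports valid empty STAR files
  scE <- simulateScene(sceneParams(nMicrographs = 1L,
                                   pairsPerMicrograph = 0L,
                                   freeAPerMicrograph = 0L,
                                   freeBPerMicrograph = 0L, seed = 1L))
  fE <- file.path(dir, "empty.star")
  writeParticles(scE$tableA, fE)
  expect_equal(nParticles(readParticles(fE)), 0L)
})

test_that("denser background dilutes the tether excess peak height", {
  peakHeight <- function(free) {
    p <- sceneParams(nMicrographs = 30L, freeAPerMicrograph = free,
                     freeBPerMicrograph = free, seed = 91L)
    sc <- simulateScene(p)
    obs <- pairDistances(pairAllMicrographs(sc$tableB, sc$tableA))
    nul <- nullPairingDistances(sc$tableB, sc$tableA, 11210, 7965,
                                replicates = 3L, seed = 92L)
    cmp <- compareToNull(obs, nul, binWidth = 20)
    # height of the excess near the tether mode, on the observed count scale
    centers <- cmp@breaks[-1] - 10
    max(excessCounts(cmp)[centers >= 140 & centers <= 260]) /
      length(obs)
  }
  h <- vapply(c(0L, 10L, 40L), peakHeight, numeric(1))
  expect_true(all(diff(h) < 0))
})
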