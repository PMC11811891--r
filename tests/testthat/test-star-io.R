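test_that("particle blocks parse into grouped records", {
  ps <- readParticles(text = starFixture(c("mic1.mrc 100 200",
                                           "mic2.mrc 300 400")),
                      pixelSizeA = 1, population = "tauA")
  expect_s4_class(ps, "ParticleSet")
  expect_equal(nParticles(ps), 2L)
  expect_equal(micrographNames(ps), c("mic1.mrc", "mic2.mrc"))
  expect_equal(population(ps), "tauA")
  # origin columns absent -> read as 0
  expect_equal(particleData(ps)$originXA, c(0, 0))

  four <- readParticles(text = starFixture(c("m1 1 2", "m2 3 4",
                                             "m1 5 6", "m2 7 8")),
                        pixelSizeA = 1)
  expect_equal(unname(table(particleData(four)$micrograph)),
               array(c(2L, 2L)))
})

test_that("format errors name the offending column or row", {
  noY <- c("data_particles", "loop_", "_rlnMicrographName #1",
           "_rlnCoordinateX #2", "m1 1")
  expect_error(readParticles(text = noY, pixelSizeA = 1),
               "_rlnCoordinateY")
  noMic <- c("data_particles", "loop_", "_rlnCoordinateX #1",
             "_rlnCoordinateY #2", "1 2")
  expect_error(readParticles(text = noMic, pixelSizeA = 1),
               "_rlnMicrographName")
  badNum <- starFixture(c("m1 1 2", "m1 oops 4"))
  expect_error(readParticles(text = badNum, pixelSizeA = 1),
               "row 2")
})

test_that("refined positions apply coord * pixel size - origin shift", {
  tags <- c("_rlnMicrographName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnOriginXAngst", "_rlnOriginYAngst")
  ps <- readParticles(
    text = starFixture(c("m1 100 50 0 0",
                         "m1 1000 50 8.22 0",
                         "m1 0 50 3.5 0"), tags),
    pixelSizeA = 0.822)
  pos <- refinedPositions(ps)
  expect_equal(pos$xA, c(100 * 0.822, 1000 * 0.822 - 8.22, -3.5))
  expect_equal(pos$xA[2], 813.78)

  # identity scaling at 1 A/px
  one <- readParticles(text = starFixture("m1 100 200"), pixelSizeA = 1)
  expect_equal(refinedPositions(one)$xA, 100)
})

test_that("refined position is affine in the picked coordinate", {
  xs <- c(10, 20, 30)
  ps <- readParticles(
    text = starFixture(sprintf("m1 %d 5", xs)), pixelSizeA = 0.822)
  xA <- refinedPositions(ps)$xA
  expect_equal(diff(xA), rep(10 * 0.822, 2))
})

test_that("legacy pixel-unit origins are converted to Angstrom", {
  tags <- c("_rlnMicrographName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnOriginX", "_rlnOriginY")
  ps <- readParticles(text = starFixture("m1 100 200 10 5", tags),
                      pixelSizeA = 2)
  expect_equal(particleData(ps)$originXA, 20)
  expect_equal(refinedPositions(ps)$xA, 100 * 2 - 20)
})

test_that("pixel size comes from the optics block and conflicts fail loud", {
  star <- c("data_optics", "loop_", "_rlnOpticsGroup #1",
            "_rlnImagePixelSize #2", "1 0.822", "",
            starFixture("m1 100 200"))
  ps <- readParticles(text = star)
  expect_equal(pixelSize(ps), 0.822)
  expect_equal(pixelSize(readParticles(text = star, pixelSizeA = 0.822)),
               0.822)
  expect_error(readParticles(text = star, pixelSizeA = 1.0), "conflict")
  expect_error(readParticles(text = starFixture("m1 1 2")),
               "pixel size is required")
})

test_that("basename-only matching strips micrograph directories", {
  ps <- readParticles(text = starFixture("Movies/job1/m1.mrc 1 2"),
                      pixelSizeA = 1, basenameOnly = TRUE)
  expect_equal(micrographNames(ps), "m1.mrc")
})

test_that("write/read round trip is the identity on particle tables", {
  # empty table
  empty <- new("ParticleSet",
               particles = data.frame(micrograph = character(0),
                                      xPx = numeric(0), yPx = numeric(0),
                                      originXA = numeric(0),
                                      originYA = numeric(0)),
               pixelSize = 0.822, population = "tauB")
  txt <- writeParticles(empty)
  back <- readParticles(text = txt, population = "tauB")
  expect_equal(nParticles(back), 0L)
  expect_equal(pixelSize(back), 0.822)

  # random 100-record table round-trips within 1e-6 A
  set.seed(11)
  tab <- data.frame(
    micrograph = sample(sprintf("mic_%02d.mrc", 1:7), 100, replace = TRUE),
    xPx = runif(100, 0, 5760), yPx = runif(100, 0, 4092),
    originXA = runif(100, -20, 20), originYA = runif(100, -20, 20))
  ps <- new("ParticleSet", particles = tab, pixelSize = 0.822,
            population = "tauA")
  back <- readParticles(text = writeParticles(ps), population = "tauA")
  expect_equal(table(particleData(back)$micrograph),
               table(tab$micrograph))
  p0 <- refinedPositions(ps); p1 <- refinedPositions(back)
  expect_lt(max(abs(p0$xA - p1$xA), abs(p0$yA - p1$yA)), 1e-6)
})

test_that("invalid particle sets are rejected by the validity method", {
  tab <- data.frame(micrograph = "m1", xPx = -1, yPx = 0,
                    originXA = 0, originYA = 0)
  expect_error(new("ParticleSet", particles = tab, pixelSize = 1,
                   population = "x"), "non-negative")
  tab$xPx <- NaN
  expect_error(new("ParticleSet", particles = tab, pixelSize = 1,
                   population = "x"), "non-finite")
  tab$xPx <- 1
  expect_error(new("ParticleSet", particles = tab, pixelSize = 0,
                   population = "x"), "positive")
})
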