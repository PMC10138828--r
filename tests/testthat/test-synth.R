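test_that("helix geometry matches the closed-form chord distances", {
  h <- makeHelix(12)
  chord <- function(r, twist, rise, m)
    sqrt((2 * r * sin(m * twist * pi / 180 / 2))^2 + (m * rise)^2)
  for (m in 2:6) {
    want <- chord(2.3, 100, 1.5, m)
    for (i in 1:(12 - m))   # exact repeat symmetry along the helix
      expect_equal(sqrt(sum((h[i, ] - h[i + m, ])^2)), want,
                   tolerance = 1e-9)
  }
  d4 <- chord(2.3, 100, 1.5, 4)
  expect_equal(d4, 6.2028, tolerance = 1e-4)
  expect_true(d4 >= 5.1 && d4 <= 6.3)            # inside the alpha band
  expect_true(chord(2.3, 100, 1.5, 3) < 5.1)     # (i,i+3) below it
  expect_true(chord(2.3, 100, 1.5, 5) > 6.3)     # (i,i+5) above it
  expect_error(makeHelix(1), ">= 2")
})

test_that("generators are seed-deterministic and leave the caller's RNG alone", {
  expect_equal(makeHelix(8, noiseSigma = 0.3, seed = 7),
               makeHelix(8, noiseSigma = 0.3, seed = 7))
  expect_false(isTRUE(all.equal(makeHelix(8, noiseSigma = 0.3, seed = 7),
                                makeHelix(8, noiseSigma = 0.3, seed = 8))))
  expect_equal(makeCoil(10, seed = 4), makeCoil(10, seed = 4))
  expect_equal(makeSheet(3, 8, shift = 1, noiseSigma = 0.2, seed = 2),
               makeSheet(3, 8, shift = 1, noiseSigma = 0.2, seed = 2))
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(makeHelix(8, noiseSigma = 0.5, seed = 1))
  expect_equal(runif(1), before)
  # noise-free output is exactly reproducible
  expect_identical(makeHelix(8), makeHelix(8))
})

test_that("noise-free ladders produce exactly the matching kernel block", {
  for (res in c(4L, 8L)) {
    lib <- kernelLibrary(res)
    for (s in 0:2) {
      shA <- makeSheet(2, res, orientation = "A", shift = s)
      cmA <- contactMap(distanceMap(frameOf(shA$coords)), betaCriterion())
      expect_equal(moleculeBlock(cmA, 1, 2),
                   kernelMatrix(lib, 2L * res + s),
                   info = sprintf("A shift %d res %d", s, res))
      shP <- makeSheet(2, res, orientation = "P", shift = s)
      cmP <- contactMap(distanceMap(frameOf(shP$coords)), betaCriterion())
      expect_equal(moleculeBlock(cmP, 1, 2), kernelMatrix(lib, s),
                   info = sprintf("P shift %d res %d", s, res))
    }
  }
  expect_error(makeSheet(2, 4, gap = 0), "positive")
  expect_error(makeSheet(2, 4, shift = 4), "shift")
})

test_that("coils respect the self-avoidance floor and the straight null", {
  w <- makeCoil(20, seed = 17)
  D <- as.matrix(dist(w))
  for (i in 1:20) for (j in 1:20)
    if (abs(i - j) >= 2) expect_gte(D[i, j], 4.0)
  # consecutive steps have the fixed length
  expect_equal(unname(D[cbind(1:19, 2:20)]), rep(3.8, 19))

  chain <- makeCoil(10, straight = TRUE)
  cm <- contactMap(distanceMap(frameOf(list(chain))), alphaCriterion())
  a <- alphaTurnAssignment(cm, 1)
  expect_equal(a$countAlpha, 0L)
  expect_equal(a$countBetaTurn, 0L)
})

test_that("assembled systems keep independent units out of contact", {
  sys <- makeSystem(synthSpec(motifs = rep("coil", 10), nRes = 8, seed = 21))
  cm <- contactMap(distanceMap(sys$frame), betaCriterion())
  am <- alignmentMatrix(cm, kernelLibrary(8))
  expect_true(all(am@P == 0L))
  expect_equal(nrow(sys$truth), 0L)

  mix <- makeSystem(synthSpec(motifs = c(rep("strand", 3), rep("coil", 7)),
                              nRes = 8, seed = 21))
  expect_equal(mix$truth$p, c(1L, 2L))
  expect_equal(mix$truth$q, c(2L, 3L))
  expect_equal(unique(mix$truth$orientation), "AP+")
})

test_that("morph trajectories interpolate between two layouts", {
  a <- makeSystem(synthSpec(motifs = "helix", nRes = 8))
  b <- list(frame = frameOf(list(makeCoil(8, straight = TRUE))))
  tr <- morphTrajectory(a, b, nFrames = 3)
  expect_length(tr, 3L)
  expect_equal(tr[[1]]@coords[[1]], a$frame@coords[[1]])
  expect_equal(tr[[3]]@coords[[1]], b$frame@coords[[1]])
  expect_equal(tr[[2]]@coords[[1]],
               (a$frame@coords[[1]] + b$frame@coords[[1]]) / 2)
  wrong <- list(frame = frameOf(list(makeCoil(9, straight = TRUE))))
  expect_error(morphTrajectory(a, wrong), "identical molecule layout")
})
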