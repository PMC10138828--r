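test_that("stability counts frames strictly above the series mean", {
  expect_equal(stabilityScore(c(10, 20, 30, 40)), 50)
  expect_equal(stabilityScore(rep(62.5, 7)), 0)
  expect_equal(stabilityScore(c(0, 100)), 50)
  expect_equal(stabilityScore(5), 0)
})

test_that("transition entropy evaluates the normalized KL divergence", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(transitionEntropy(x, x), 0)
  expect_equal(transitionEntropy(1, 1), 0)
  got <- transitionEntropy(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(got, 0.5 * log2(2) + 0.5 * log2(2 / 3), tolerance = 1e-12)
  expect_equal(round(got, 4), 0.2075)
  expect_equal(transitionEntropy(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_error(transitionEntropy(c(-1, 1), c(1, 1)), "non-negative")
  expect_error(transitionEntropy(1:3, 1:4), "equal length")
  # non-negative on random normalized pairs (Gibbs inequality)
  set.seed(31)
  for (i in 1:25) {
    b <- runif(12); a <- runif(12)
    expect_gte(transitionEntropy(b, a), 0)
  }
  # raw (unnormalized) mode is available and differs in general
  expect_false(isTRUE(all.equal(
    transitionEntropy(c(2, 2), c(1, 3), normalize = FALSE),
    transitionEntropy(c(2, 2), c(1, 3)))))
})

test_that("mutual information has its information-theoretic properties", {
  set.seed(13)
  x <- runif(200)
  h <- function(v, nb = 10) {
    br <- seq(min(v), max(v), length.out = nb + 1)
    p <- table(findInterval(v, br, rightmost.closed = TRUE,
                            all.inside = TRUE)) / length(v)
    -sum(p * log2(p))
  }
  expect_equal(mutualInformation(x, x), h(x), tolerance = 1e-12)
  expect_equal(mutualInformation(rep(1, 10), runif(10)), 0)
  for (i in 1:50) {
    a <- rnorm(40); b <- rnorm(40)
    mi <- mutualInformation(a, b)
    expect_gte(mi, 0)
    expect_equal(mi, mutualInformation(b, a), tolerance = 1e-12)
    expect_lte(mi, min(h(a), h(b)) + 1e-9)
  }
  # hand-built 4-frame joint: a,b binned to (1,1),(1,2),(2,1),(2,2)
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  expect_equal(mutualInformation(a, b, nBins = 2), 0)    # independent uniform
  expect_equal(mutualInformation(a, a, nBins = 2), 1)    # H = 1 bit
})

test_that("organizational ratios guard their divisions", {
  tal <- data.frame(frame = 0:3, P = c(10, 0, 5, 0),
                    APplus = c(6, 0, 0, 4), APminus = c(4, 0, 0, 1))
  r <- organizationalIndex(tal)
  expect_equal(r$apToTotal, c(0.5, 0, 0, 1))
  expect_equal(r$orgIndex[1], 1)
  expect_true(is.na(r$orgIndex[2]))   # nothing classified
  expect_equal(r$orgIndex[3], 0)
  expect_true(is.na(r$orgIndex[4]))   # AP only: index undefined
})

test_that("shift profiles recover the generator's register shifts", {
  lib <- kernelLibrary(8)
  ams <- lapply(c(0L, 2L), function(s) {
    sys <- makeSystem(synthSpec(motifs = rep("strand", 3), nRes = 8,
                                orientation = "P", shift = s))
    cm <- contactMap(distanceMap(sys$frame), betaCriterion())
    alignmentMatrix(cm, lib)
  })
  sp <- shiftProfile(ams)
  expect_equal(sp$class, c("P", "P"))
  expect_equal(sp$shift, c(0L, 2L))
  expect_equal(sp$count, c(2L, 2L))
  expect_equal(sp$frame, c(0L, 1L))
  empty <- shiftProfile(list(), integer(0))
  expect_equal(nrow(empty), 0L)
})

test_that("series summaries report max, frames-at-max, mean and stability", {
  s <- summarizeSeries(c(50, 50, 25, 0))
  expect_equal(s$max, 50)
  expect_equal(s$framesAtMax, 2L)
  expect_equal(s$mean, 31.25)
  expect_equal(s$stability, 50)
  const <- summarizeSeries(rep(62.5, 4))
  expect_equal(const$framesAtMax, 4L)
  expect_equal(const$stability, 0)
  expect_equal(summarizeSeries(42)$framesAtMax, 1L)
  two <- summarizeSeries(cbind(c(1, 2), c(3, 3)))
  expect_equal(two$molecule, 1:2)
  expect_equal(two$mean, c(1.5, 3))
})

test_that("helix score series track per-frame structural content", {
  helixSys <- makeSystem(synthSpec(motifs = "helix", nRes = 8))
  chain <- list(frame = frameOf(list(makeCoil(8, straight = TRUE))))
  frames <- morphTrajectory(helixSys, chain, nFrames = 4)
  ser <- helixScoreSeries(frames)
  expect_equal(length(ser@frames), 4L)
  expect_equal(ser@alpha[1, 1], 100)   # ideal helix fully covered
  expect_equal(ser@alpha[4, 1], 0)     # extended chain has no alpha
  expect_true(all(diff(ser@alpha[, 1]) <= 0))
  # constant geometry gives a constant series
  static <- helixScoreSeries(list(frames[[1]], frames[[1]], frames[[1]]))
  expect_equal(static@alpha[, 1], rep(100, 3))
  expect_equal(stabilityScore(static@alpha[, 1]), 0)
})
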