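test_that("helix/turn scanning classifies contacts by sequence gap", {
  # four (i, i+4) contacts on an 8-mer: all alpha, pace exactly 4
  a <- alphaTurnAssignment(
    cmIntra(8, list(c(1, 5), c(2, 6), c(3, 7), c(4, 8))), 1)
  expect_equal(a$countAlpha, 4L)
  expect_equal(a$paceHelix, 4)
  expect_equal(a$countBetaTurn, 0L)
  expect_equal(a$helixResidues, 1:8)

  # a single long-range contact is a turn with its full gap as length
  b <- alphaTurnAssignment(cmIntra(8, list(c(1, 8))), 1)
  expect_equal(b$countAlpha, 0L)
  expect_equal(b$countBetaTurn, 1L)
  expect_equal(b$lengthBetaTurn, 7)

  # empty map: all counters zero
  e <- alphaTurnAssignment(cmIntra(8, list()), 1)
  expect_equal(e$countAlpha, 0L)
  expect_equal(e$countBetaTurn, 0L)
  expect_true(is.na(e$paceHelix))

  # the incremental mean is recency-weighted: gaps 4, 5, 4 scanned in row
  # order give ((4*2) + (5*1+4)/2) / 3 = 12.5/3, not the plain mean 13/3
  m <- alphaTurnAssignment(cmIntra(12, list(c(1, 5), c(1, 6), c(2, 6))), 1)
  expect_equal(m$countAlpha, 3L)
  expect_equal(m$paceHelix, 12.5 / 3)
})

test_that("content percentages cover the union of contact spans", {
  one <- alphaTurnAssignment(cmIntra(8, list(c(1, 5))), 1)
  expect_equal(helixContent(one, 8), 62.5)      # 5 of 8 residues
  expect_equal(turnContent(one, 8), 0)
  none <- alphaTurnAssignment(cmIntra(8, list()), 1)
  expect_equal(helixContent(none, 8), 0)
  full <- alphaTurnAssignment(cmIntra(8, list(c(1, 5), c(4, 8))), 1)
  expect_equal(helixContent(full, 8), 100)
})

test_that("strand-pair reduction vectors and projection behave as printed", {
  lib <- kernelLibrary(4)
  antiCm <- cmFromBlock(kernelMatrix(lib, 8))      # anti-diagonal block
  expect_equal(strandRowVector(antiCm, 1, 2), rep(1, 4))
  expect_equal(strandColVector(antiCm, 1, 2), rep(1, 4))
  zeroCm <- cmFromBlock(matrix(0, 4, 4))
  expect_equal(strandRowVector(zeroCm, 1, 2), rep(0, 4))
  B <- matrix(0, 4, 4); B[1, 2] <- 1; B[3, 2] <- 1
  expect_equal(strandRowVector(cmFromBlock(B), 1, 2), c(0, 2, 0, 0))
  expect_equal(strandColVector(cmFromBlock(B), 1, 2), c(1, 0, 1, 0))

  expect_equal(tripletProjection(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tripletProjection(rep(1, 4), rep(1, 4)), 4)
  expect_equal(tripletProjection(rep(0, 4), c(1, 2, 3, 4)), 0)
  expect_error(tripletProjection(1:3, 1:4), "equal length")
})

test_that("three in-register strands yield one confirmed triplet", {
  sys <- makeSystem(synthSpec(motifs = rep("strand", 3), nRes = 4,
                              orientation = "A", shift = 0))
  cm <- contactMap(distanceMap(sys$frame), betaCriterion())
  am <- alignmentMatrix(cm, kernelLibrary(4), minContact = 1)
  dom <- betaSheetDomains(am, cm)
  expect_equal(nrow(dom@pairs), 2L)
  expect_equal(dom@triplets$p, 1L)
  expect_equal(dom@triplets$q, 2L)
  expect_equal(dom@triplets$s, 3L)
  expect_true(dom@triplets$projection > 0)
  expect_equal(dom@pairs$runLength, c(4L, 4L))
  expect_true(all(dom@pairs$orientation %in% c("AP+", "AP-")))
  expect_equal(dom@pairs$shift, c(0L, 0L))
})

test_that("two strands give a pair but no triplet; empty systems give nothing", {
  two <- makeSystem(synthSpec(motifs = rep("strand", 2), nRes = 6,
                              orientation = "P", shift = 1))
  cm <- contactMap(distanceMap(two$frame), betaCriterion())
  am <- alignmentMatrix(cm, kernelLibrary(6))
  dom <- betaSheetDomains(am, cm)
  expect_equal(nrow(dom@pairs), 1L)
  expect_equal(nrow(dom@triplets), 0L)
  expect_equal(dom@pairs$orientation, "P")
  expect_equal(dom@pairs$shift, 1L)

  lone <- makeSystem(synthSpec(motifs = rep("coil", 4), nRes = 6, seed = 9))
  cmL <- contactMap(distanceMap(lone$frame), betaCriterion())
  amL <- alignmentMatrix(cmL, kernelLibrary(6))
  domL <- betaSheetDomains(amL, cmL)
  expect_equal(nrow(domL@pairs), 0L)
  expect_equal(peptidesInBeta(domL), 0)
})

test_that("peptide-in-sheet fractions count the union of sheet members", {
  sys <- makeSystem(synthSpec(motifs = c(rep("strand", 3), rep("coil", 7)),
                              nRes = 8, seed = 3))
  cm <- contactMap(distanceMap(sys$frame), betaCriterion())
  am <- alignmentMatrix(cm, kernelLibrary(8))
  dom <- betaSheetDomains(am, cm)
  expect_equal(peptidesInBeta(dom), 0.3)
  expect_equal(peptidesInBeta(dom, nmol = 5), 3 / 5)
})

test_that("molecule relabeling permutes secondary-structure calls consistently", {
  spec <- synthSpec(motifs = c("strand", "strand", "helix"), nRes = 8)
  sys <- makeSystem(spec)
  perm <- c(3L, 1L, 2L)
  permFrame <- frameOf(sys$frame@coords[perm])
  cm1 <- contactMap(distanceMap(sys$frame), betaCriterion())
  cm2 <- contactMap(distanceMap(permFrame), betaCriterion())
  am1 <- alignmentMatrix(cm1, kernelLibrary(8))
  am2 <- alignmentMatrix(cm2, kernelLibrary(8))
  # pair (1,2) in the original is pair (2,3) after permutation
  expect_equal(am2@P[2, 3], am1@P[1, 2])
  cmA1 <- contactMap(distanceMap(sys$frame), alphaCriterion())
  cmA2 <- contactMap(distanceMap(permFrame), alphaCriterion())
  expect_equal(alphaTurnAssignment(cmA2, 1)$countAlpha,
               alphaTurnAssignment(cmA1, 3)$countAlpha)
})
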