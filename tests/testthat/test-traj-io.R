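test_that("a synthetic system round-trips through PDB at format precision", {
  sys <- makeSystem(synthSpec(motifs = c("strand", "strand", "helix"),
                              nRes = 6))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(sys$frame, pdb)
  sess <- loadSession(pdb)
  expect_equal(nFrames(sess), 1L)
  expect_equal(molLengths(sess), rep(6L, 3))
  got <- sampleFrames(sess, 1)[[1]]
  for (m in 1:3)
    expect_equal(frameCoords(got)[[m]], sys$frame@coords[[m]],
                 tolerance = 1e-2)
})

test_that("multi-model PDB trajectories load with one frame per model", {
  a <- makeSystem(synthSpec(motifs = "helix", nRes = 8))
  b <- list(frame = frameOf(list(makeCoil(8, step = 3.8, straight = TRUE))))
  traj <- morphTrajectory(a, b, nFrames = 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(traj, pdb)
  sess <- loadSession(pdb)
  expect_equal(nFrames(sess), 5L)
  # separate topology + trajectory files also work
  top <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(traj[[1]], top)
  sess2 <- loadSession(top, trajPath = pdb)
  expect_equal(nFrames(sess2), 5L)
  expect_equal(sess2@frames[[3]], sess@frames[[3]])
})

test_that("GRO files parse with nm-to-Angstrom conversion and chain splits", {
  # two 3-residue molecules, residue numbering restarting at the second
  gro <- withr::local_tempfile(fileext = ".gro")
  atom <- function(resno, resnm, name, num, x, y, z)
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resno, resnm, name, num, x, y, z)
  writeLines(c(
    "synthetic two-chain system", "    6",
    atom(1, "ALA", "BB", 1, 0.0, 0.0, 0.0),
    atom(2, "GLY", "BB", 2, 0.35, 0.0, 0.0),
    atom(3, "ALA", "BB", 3, 0.70, 0.0, 0.0),
    atom(1, "LEU", "BB", 4, 0.0, 0.48, 0.0),
    atom(2, "ALA", "BB", 5, 0.35, 0.48, 0.0),
    atom(3, "LYS", "BB", 6, 0.70, 0.48, 0.0),
    "   5.00000   5.00000   5.00000"), gro)
  sess <- loadSession(gro)
  expect_equal(molLengths(sess), c(3L, 3L))
  fr <- sampleFrames(sess)[[1]]
  expect_equal(frameCoords(fr)[[1]][2, ], c(3.5, 0, 0))
  expect_equal(frameCoords(fr)[[2]][1, ], c(0, 4.8, 0))
  expect_equal(exploreSystem(sess)@sequences[[2]], c("LEU", "ALA", "LYS"))
})

test_that("system summaries tally molecules by length", {
  sys <- makeSystem(synthSpec(motifs = rep("coil", 10), nRes = 8, seed = 1))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(sys$frame, pdb)
  summ <- exploreSystem(loadSession(pdb))
  expect_equal(summ@lenDict, c("8" = 10L))
  expect_equal(summ@peptideLengthList, rep(8L, 10))

  # mixed lengths: one 4-mer and one 6-mer
  mixed <- frameOf(list(makeCoil(4, seed = 2), makeCoil(6, seed = 3)))
  writeFramesPDB(mixed, pdb)
  summ2 <- exploreSystem(loadSession(pdb))
  expect_equal(summ2@lenDict, c("4" = 1L, "6" = 1L))
})

test_that("frame sampling follows the stride contract", {
  a <- makeSystem(synthSpec(motifs = "helix", nRes = 8))
  b <- list(frame = frameOf(list(makeCoil(8, straight = TRUE))))
  traj <- morphTrajectory(a, b, nFrames = 10)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(traj, pdb)
  sess <- loadSession(pdb)

  idx <- function(fs) vapply(fs, function(f) f@frameIndex, integer(1))
  expect_equal(idx(sampleFrames(sess, 1)), 0:9)
  expect_equal(idx(sampleFrames(sess, 4)), c(0L, 4L, 8L))
  expect_equal(idx(sampleFrames(sess, 100)), 0L)
  expect_error(sampleFrames(sess, 0), "positive")
  # idempotent and |sampled| = floor((F-1)/interval) + 1
  for (iv in 1:10) {
    s1 <- sampleFrames(sess, iv)
    expect_length(s1, (10 - 1) %/% iv + 1)
    expect_equal(idx(s1), idx(sampleFrames(sess, iv)))
  }
})

test_that("unusable inputs fail with informative errors", {
  sys <- makeSystem(synthSpec(motifs = "helix", nRes = 8))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeFramesPDB(sys$frame, pdb)
  expect_error(loadSession(pdb, selection = "ZZ"), "zero atoms")
  expect_error(loadSession("no/such/file.pdb"), "not found")
  expect_error(loadSession(pdb, trajPath = "no/such.dcd"), "not found")
  bad <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("junk", "not-a-number"), bad)
  expect_error(loadSession(bad), "cannot parse GRO")
  xtc <- withr::local_tempfile(fileext = ".xtc")
  file.create(xtc)
  expect_error(loadSession(pdb, trajPath = xtc), "no reader")
})
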