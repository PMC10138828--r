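test_that("distance maps reproduce elementary geometry", {
  fr <- frameOf(list(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 0))))
  D <- distanceMap(fr)@D
  expect_equal(D[1, 2], 5)          # 3-4-5 triangle
  expect_equal(D[2, 3], 0)          # identical points
  chain <- frameOf(list(cbind(c(0, 3.8, 7.6), 0, 0)))
  expect_equal(distanceMap(chain)@D[1, 3], 7.6)  # additivity on a line
  bad <- frameOf(list(rbind(c(0, 0, 0), c(1, 0, 0))))
  bad@coords[[1]][2, 1] <- NaN
  expect_error(distanceMap(bad), "molecule 1")
})

test_that("contact maps agree with a brute-force double loop", {
  set.seed(11)
  for (trial in 1:5) {
    coords <- list(matrix(rnorm(8 * 3, sd = 4), 8),
                   matrix(rnorm(8 * 3, sd = 4), 8))
    dm <- distanceMap(frameOf(coords))
    for (crit in list(betaCriterion(5.3), alphaCriterion(5.1, 6.3, 3))) {
      got <- contactMap(dm, crit)@contacts
      n <- 16
      molOf <- rep(1:2, each = 8)
      resOf <- rep(1:8, 2)
      want <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n) {
        if (i == j) next
        d <- dm@D[i, j]
        hit <- if (crit@kind == "beta") {
          d <= crit@dHigh &&
            !(molOf[i] == molOf[j] && abs(resOf[i] - resOf[j]) < crit@minSep)
        } else {
          molOf[i] == molOf[j] && abs(resOf[i] - resOf[j]) >= crit@minSep &&
            d >= crit@dLow && d <= crit@dHigh
        }
        if (hit) want[i, j] <- 1
      }
      expect_equal(got, want)
    }
  }
})

test_that("beta contacts are monotone in the threshold and rigid-motion invariant", {
  set.seed(7)
  coords <- list(matrix(rnorm(30, sd = 3), 10))
  dm <- distanceMap(frameOf(coords))
  prev <- contactMap(dm, betaCriterion(3.0))@contacts
  for (d0 in c(4, 5.3, 7, 12)) {
    cur <- contactMap(dm, betaCriterion(d0))@contacts
    expect_true(all(cur - prev >= 0))  # raising d0 never removes a contact
    prev <- cur
  }
  # counts are even (symmetry) and survive rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- list(coords[[1]] %*% R + matrix(c(5, -3, 2), 10, 3, byrow = TRUE))
  cm1 <- contactMap(dm, betaCriterion())
  cm2 <- contactMap(distanceMap(frameOf(moved)), betaCriterion())
  expect_equal(sum(cm1@contacts) %% 2, 0)
  expect_equal(sum(cm1@contacts), sum(cm2@contacts))
})

test_that("the alpha band excludes distances below its lower edge", {
  # two residues of one molecule at exactly 5.0 A, separation 4
  coords <- list(cbind(c(0, 100, 200, 300, 5), 0, 0))
  cm <- contactMap(distanceMap(frameOf(coords)), alphaCriterion(5.1, 6.3))
  expect_equal(sum(cm@contacts), 0)  # 5.0 below the band
  # and beta at d0 = 5.3 includes 5.0
  cmB <- contactMap(distanceMap(frameOf(coords)), betaCriterion(5.3))
  expect_equal(cmB@contacts[1, 5], 1)
})

test_that("molecule blocks index residues of p by row and q by column", {
  # single inter-molecular contact: residue 1 of mol 1, residue 4 of mol 2
  c1 <- cbind(c(0, 50, 100, 150), 0, 0)
  c2 <- cbind(c(330, 220, 110, 0), 4.8, 0)
  cm <- contactMap(distanceMap(frameOf(list(c1, c2))), betaCriterion())
  B <- moleculeBlock(cm, 1, 2)
  want <- matrix(0, 4, 4); want[1, 4] <- 1
  expect_equal(B, want)
  expect_equal(moleculeBlock(cm, 2, 1), t(B))
  far <- frameOf(list(c1, c2 + 1000))
  cmFar <- contactMap(distanceMap(far), betaCriterion())
  expect_equal(sum(moleculeBlock(cmFar, 1, 2)), 0)
  uneq <- frameOf(list(c1, cbind(1:3, 500, 0)))
  expect_error(moleculeBlock(contactMap(distanceMap(uneq), betaCriterion()),
                             1, 2), "square blocks")
})

test_that("contact maps export as TSV edge lists with distances", {
  sh <- makeSheet(2, 4)
  cm <- contactMap(distanceMap(frameOf(sh$coords)), betaCriterion())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeContactsTSV(cm, tsv)
  df <- read.delim(tsv)
  expect_setequal(names(df),
                  c("i", "j", "mol_i", "res_i", "mol_j", "res_j", "distance"))
  expect_equal(nrow(df), sum(cm@contacts) / 2)
  inter <- df[df$mol_i == 1 & df$mol_j == 2, ]
  expect_true(all(abs(inter$distance - 4.8) < 1e-6))
})
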