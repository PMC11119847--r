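# Pairwise placement energies and their binarization.

test_that("binarization applies the conn-then-clash rules verbatim", {
  cases <- data.frame(
    bonded = c(TRUE,  TRUE,  TRUE,  FALSE, FALSE, TRUE,  FALSE),
    EB     = c(-2,    600,   500,   NA,    NA,    499.9, NA),
    ENB    = c(900,   700,   900,   -1,    501,   100,   500),
    conn   = c(-1L,   0L,    -1L,   0L,    0L,    -1L,   0L),
    clash  = c(0L,    1L,    0L,    0L,    1L,    0L,    0L))
  got <- binarizePairEnergies(cases[, 1:3], thE = 500)
  expect_equal(got$conn, cases$conn)
  expect_equal(got$clash, cases$clash)
  # exclusivity: clash * conn = 0 always
  expect_true(all(got$clash * got$conn == 0))
  expect_error(binarizePairEnergies(cases[, 1:3], thE = -1), "positive")
})

test_that("geometric pair terms follow the distance rules", {
  fr <- butaneFragmentation()
  f1 <- fragments(fr)[[1]]; f2 <- fragments(fr)[[2]]
  x1 <- coordMatrix(f1@compound); x2 <- coordMatrix(f2@compound)

  # native chain geometry: attachment atoms at the C-C bond length
  gt <- geometricPairTerms(f1, x1, f2, x2)
  expect_equal(gt$conn, -1L)
  expect_equal(gt$clash, 0L)

  # far apart: (0, 0)
  gt <- geometricPairTerms(f1, x1, f2, translatePose(x2, c(12, 0, 0)))
  expect_equal(gt$conn, 0L)
  expect_equal(gt$clash, 0L)

  # overlapping but not connectable (attachment atoms 2.5 A apart,
  # outside the bond window; bodies on top of each other): clash
  gt <- geometricPairTerms(f1, x1, f2,
                           translatePose(x2, c(-3.8, 0, 0)))
  expect_equal(gt$conn, 0L)
  expect_equal(gt$clash, 1L)

  # attachment distance outside the window but heavy atoms close: clash,
  # not conn
  gt <- geometricPairTerms(f1, x1, f2, translatePose(x2, c(-1.2, 0, 0)),
                           bondWindow = c(1.2, 2.0))
  expect_equal(gt$conn, 0L)
})

test_that("ENB captures the distant, contact and overlap regimes", {
  fr <- butaneFragmentation()
  f1 <- fragments(fr)[[1]]; f2 <- fragments(fr)[[2]]
  x1 <- coordMatrix(f1@compound); x2 <- coordMatrix(f2@compound)

  # far beyond the non-bonded cutoff: ~0
  expect_lt(abs(computeENB(f1, x1, f2, translatePose(x2, c(40, 0, 0)))),
            0.05)
  # van-der-Waals contact: small, attractive
  enbContact <- computeENB(f1, x1, f2, translatePose(x2, c(3.5, 0, 0)))
  expect_lt(enbContact, 0)
  expect_gt(enbContact, -5)
  # heavy-atom overlap at ~0.5 A: enormous repulsion
  enbOverlap <- computeENB(f1, x1, f2, translatePose(x1, c(0.5, 0, 0)))
  expect_gt(enbOverlap, 500)
})

test_that("ENB grows monotonically as fragments are pushed into overlap", {
  fr <- butaneFragmentation()
  f1 <- fragments(fr)[[1]]; f2 <- fragments(fr)[[2]]
  x1 <- coordMatrix(f1@compound); x2 <- coordMatrix(f2@compound)
  # side-by-side approach: the copy slides in along y, so the closest
  # contact shrinks with the separation and repulsion must grow
  seps <- c(3.6, 3.2, 2.8, 2.4)
  enbs <- vapply(seps, function(s)
    computeENB(f1, x1, f2, translatePose(x1, c(0, s, 0))), numeric(1))
  expect_true(all(enbs > 0))
  expect_true(all(diff(enbs) > 0))
})

test_that("EB is small for ideal bond geometry and diverges when stretched", {
  fr <- butaneFragmentation()
  f1 <- fragments(fr)[[1]]; f2 <- fragments(fr)[[2]]
  x1 <- coordMatrix(f1@compound); x2 <- coordMatrix(f2@compound)

  # native chain geometry: undistorted bond
  ebIdeal <- computeEB(f1, x1, f2, x2)
  expect_lt(abs(ebIdeal), 500)
  # attachment atoms ~6 A apart: bond-stretch energy dominates
  ebStretch <- computeEB(f1, x1, f2, translatePose(x2, c(6, 0, 0)))
  expect_gt(ebStretch, 500)
  # symmetry of the pair energies
  expect_equal(computeEB(f2, x2, f1, x1), ebIdeal, tolerance = 1e-6)
  expect_equal(computeENB(f2, x2, f1, x1), computeENB(f1, x1, f2, x2),
               tolerance = 1e-6)

  # unbonded fragments have no EB
  expect_error(computeEB(f1, x1, f1, x1), "different|not bonded")
})

test_that("the distance prefilter never disagrees with the energy path", {
  fr <- butaneFragmentation()
  set.seed(21)
  entries <- list()
  for (k in 1:2) {
    f <- fragments(fr)[[k]]
    native <- coordMatrix(f@compound)
    for (d in 1:3) {
      entries[[length(entries) + 1L]] <- list(
        fragment = k, score = -runif(1, 1, 5),
        coords = translatePose(native, rnorm(3, 0, 5)))
    }
  }
  ps <- placementSet(entries, fr)
  withPre <- pairTerms(ps, mode = "energy", prefilterCutoff = 8)
  noPre <- pairTerms(ps, mode = "energy", prefilterCutoff = Inf)
  expect_equal(withPre$clash, noPre$clash)
  expect_equal(withPre$conn, noPre$conn)
  # prefiltered pairs carry no energies (the stated optimization)
  expect_true(any(is.na(withPre$ENB)))
  expect_true(all(!is.na(noPre$ENB)))
})

test_that("prefilter decides far pairs and defers near ones", {
  fr <- butaneFragmentation()
  f1 <- fragments(fr)[[1]]; f2 <- fragments(fr)[[2]]
  x1 <- coordMatrix(f1@compound); x2 <- coordMatrix(f2@compound)

  far <- pairPrefilter(f1, x1, f2, translatePose(x2, c(15, 0, 0)), 8)
  expect_true(far$decided)
  expect_equal(c(far$clash, far$conn), c(0L, 0L))

  near <- pairPrefilter(f1, x1, f2, translatePose(x2, c(3, 0, 0)), 8)
  expect_false(near$decided)

  # bonded pair, attachment atoms ~10 A apart but bodies within cutoff:
  # conn is decided 0 without any energy call, clash deferred
  mid <- pairPrefilter(f1, x1, f2, translatePose(x2, c(0, 7, 0)), 8)
  expect_false(mid$decided)
  expect_true(mid$connDecided)
  expect_equal(mid$conn, 0L)
})
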