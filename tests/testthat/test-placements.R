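# Subregion grid, pose ingestion and RMSD deduplication.

test_that("subregion enumeration tiles the box exactly", {
  r14 <- dockingRegion(c(16.61, -7.03, 14.45), 14, 2)
  sub <- enumerateSubregions(r14)
  expect_equal(nrow(sub), 343)

  expect_equal(nrow(enumerateSubregions(dockingRegion(c(0, 0, 0), 2, 2))), 1)
  one <- enumerateSubregions(dockingRegion(c(1, 2, 3), 2, 2))
  expect_equal(unlist(one[1, c("cx", "cy", "cz")], use.names = FALSE),
               c(1, 2, 3))
  expect_equal(nrow(enumerateSubregions(dockingRegion(c(0, 0, 0), 4, 2))), 8)

  expect_error(enumerateSubregions(dockingRegion(c(0, 0, 0), 5, 2)),
               "integer multiple")

  # tiling: cell centers form the full lattice and are pairwise distinct
  expect_equal(anyDuplicated(sub[, c("ix", "iy", "iz")]), 0L)
  expect_equal(range(sub$cx), c(16.61 - 6, 16.61 + 6))
  # a point maps to exactly one cell and that cell contains it
  p <- c(17.2, -6.1, 12.0)
  idx <- quboDock:::.subregionOf(r14, p)
  row <- sub[sub$ix == idx[1] & sub$iy == idx[2] & sub$iz == idx[3], ]
  expect_equal(nrow(row), 1)
  expect_true(all(abs(p - unlist(row[, c("cx", "cy", "cz")])) <= 1 + 1e-12))
})

makePoseEntries <- function(fr, specs) {
  # specs: data.frame(fragment, score, dx)
  lapply(seq_len(nrow(specs)), function(i) {
    f <- fragments(fr)[[specs$fragment[i]]]
    list(fragment = specs$fragment[i], score = specs$score[i],
         coords = translatePose(coordMatrix(f@compound),
                                c(specs$dx[i], 0, 0)))
  })
}

test_that("pose ingestion filters scores, caps per subregion, drops outsiders", {
  fr <- butaneFragmentation()
  region <- dockingRegion(c(0, 0, 0), 14, 2)

  # positive score dropped
  ps <- ingestPoses(makePoseEntries(fr, data.frame(
    fragment = c(1, 1), score = c(0.5, -1), dx = c(0, 0.5))),
    fr, region)
  expect_equal(nrow(placementTable(ps)), 1)
  expect_equal(placementTable(ps)$score, -1)

  # 25 poses of one fragment in one subregion -> 20 best kept
  specs <- data.frame(fragment = 1, score = -(1:25) / 10, dx = 0)
  ps <- ingestPoses(makePoseEntries(fr, specs), fr, region)
  expect_equal(nrow(placementTable(ps)), 20)
  expect_equal(sort(placementTable(ps)$score), sort(-(6:25) / 10))

  # centroid outside the box dropped with warning
  expect_warning(
    ps <- ingestPoses(makePoseEntries(fr, data.frame(
      fragment = 1, score = -1, dx = 50)), fr, region),
    "outside")
  expect_equal(nrow(placementTable(ps)), 0)

  # unknown fragment and missing score raise errors
  bad <- makePoseEntries(fr, data.frame(fragment = 1, score = -1, dx = 0))
  bad[[1]]$fragment <- 9L
  expect_error(ingestPoses(bad, fr, region), "unknown fragment")
  bad2 <- makePoseEntries(fr, data.frame(fragment = 1, score = -1, dx = 0))
  bad2[[1]]$score <- NA_real_
  expect_error(ingestPoses(bad2, fr, region), "score")
})

test_that("pose ingestion reads score properties from SDF files", {
  inst <- generateInstance(generatorConfig(K = 2, m = 3, seed = 11))
  f <- tempfile(fileext = ".sdf")
  writePlacementsSDF(inst@placements, f)
  region <- dockingRegion(c(2, 0, 0.5), 30, 2)
  ps <- ingestPoses(f, inst@fragmentation, region)
  expect_equal(nrow(placementTable(ps)), nrow(placementTable(inst@placements)))
  expect_equal(sort(placementTable(ps)$score),
               sort(placementTable(inst@placements)$score), tolerance = 1e-6)
})

test_that("deduplication keeps best-scoring representatives", {
  fr <- butaneFragmentation()
  f1 <- fragments(fr)[[1]]
  native <- coordMatrix(f1@compound)
  mk <- function(score, dx) list(fragment = 1L, score = score,
                                 coords = translatePose(native, c(dx, 0, 0)))

  # exact duplicates: best survives
  ps <- placementSet(list(mk(-2, 0), mk(-1, 0)), fr)
  dd <- dedupPlacements(ps, 1.0)
  expect_equal(placementTable(dd)$score, -2)

  # far apart: both survive
  ps <- placementSet(list(mk(-2, 0), mk(-1, 5)), fr)
  expect_equal(nrow(placementTable(dedupPlacements(ps, 1.0))), 2)

  # collinear chain at 0.6 A spacing, scores -3, -1, -2: greedy
  # best-first accepts pose 1 (-3), rejects pose 2 (0.6 A from 1),
  # accepts pose 3 (1.2 A from 1)
  ps <- placementSet(list(mk(-3, 0), mk(-1, 0.6), mk(-2, 1.2)), fr)
  dd <- dedupPlacements(ps, 1.0)
  expect_equal(sort(placementTable(dd)$score), c(-3, -2))
})

test_that("deduplication is idempotent and keeps each fragment's best pose", {
  set.seed(5)
  for (rep in 1:5) {
    inst <- generateInstance(generatorConfig(K = 3, m = 6,
                                             displacement = 1.0,
                                             seed = 100 + rep))
    ps <- inst@placements
    dd <- dedupPlacements(ps, 1.0)
    dd2 <- dedupPlacements(dd, 1.0)
    expect_equal(placementTable(dd)[, c("fragment", "score")],
                 placementTable(dd2)[, c("fragment", "score")])
    for (k in 1:3) {
      best <- min(placementTable(ps)$score[placementTable(ps)$fragment == k])
      expect_true(best %in%
        placementTable(dd)$score[placementTable(dd)$fragment == k])
    }
  }
})
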