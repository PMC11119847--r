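# Pose assembly, redocking RMSD and pose relaxation.

test_that("assembly restores the parent graph for valid solutions", {
  set.seed(13)
  for (rep in 1:5) {
    inst <- generateInstance(generatorConfig(K = sample(2:4, 1),
                                             m = sample(2:3, 1),
                                             seed = 400 + rep))
    q <- buildQUBO(inst@placements, inst@terms)
    pool <- postprocessFilter(
      simulatedAnneal(q, restarts = 40, sweeps = 60, seed = rep), q)
    for (r in seq_len(min(nrow(solutionMatrix(pool)), 4))) {
      pose <- assemblePose(solutionMatrix(pool)[r, ], inst@placements)
      expect_true(quboDock:::.isIsomorphic(pose@compound, inst@compound))
      # no cap hydrogens remain at formed bonds: atom counts match parent
      expect_equal(nrow(atomTable(pose@compound)),
                   nrow(atomTable(inst@compound)))
    }
  }
})

test_that("assembly of the planted solution reproduces the native pose", {
  inst <- generateInstance(generatorConfig(K = 3, m = 3, seed = 19))
  pose <- assemblePose(inst@planted, inst@placements)
  # native geometry: assembled bond lengths equal the chain bond length
  b <- bondTable(pose@compound)
  xyz <- coordMatrix(pose@compound)
  heavy <- atomTable(pose@compound)$elem != "H"
  cc <- b[heavy[b$a1] & heavy[b$a2], ]
  lens <- sqrt(rowSums((xyz[cc$a1, ] - xyz[cc$a2, ])^2))
  expect_true(all(lens > 1.2 & lens < 2.0))
  expect_equal(computeRMSD(pose, inst@compound)$rmsd, 0, tolerance = 1e-9)

  # invalid selections are rejected
  bad <- inst@planted
  bad[which(bad == 0)[1]] <- 1L
  expect_error(assemblePose(bad, inst@placements), "one placement")
})

test_that("a single-fragment compound assembles to its selected placement", {
  fr <- decompose(quboDock:::.idealAlkane(2))
  expect_length(fragments(fr), 1)
  native <- coordMatrix(fragments(fr)[[1]]@compound)
  ps <- placementSet(list(list(fragment = 1L, score = -2,
                               coords = translatePose(native, c(1, 2, 3)))),
                     fr)
  pose <- assemblePose(c(1L), ps)
  expect_equal(nrow(atomTable(pose@compound)), nrow(native))
  expect_equal(coordMatrix(pose@compound),
               translatePose(native, c(1, 2, 3)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("redocking RMSD is a metric computed without superposition", {
  inst <- generateInstance(generatorConfig(K = 2, m = 2, seed = 29))
  pose <- assemblePose(inst@planted, inst@placements)

  expect_equal(computeRMSD(pose, inst@compound)$rmsd, 0)

  shifted <- pose
  shifted@compound@coords <- translatePose(coordMatrix(pose), c(1, 0, 0))
  expect_equal(computeRMSD(shifted, inst@compound)$rmsd, 1.0,
               tolerance = 1e-9)

  # symmetry in the two arguments
  a <- pose@compound; b <- inst@compound
  a@coords <- translatePose(a@coords, c(0.7, -0.2, 0.1))
  expect_equal(computeRMSD(a, b)$rmsd, computeRMSD(b, a)$rmsd,
               tolerance = 1e-9)
})

test_that("symmetry correction maps equivalent atoms onto each other", {
  benz <- loadCompound("c1ccccc1")
  fr <- decompose(benz)
  ring <- fragments(fr)[[1]]@compound
  # place an ideal hexagon in 3D
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  ring@coords <- xyz
  rotated <- ring
  rotated@coords <- rotatePoseZ(xyz, 60, c(0, 0, 0))
  # a 60-degree ring rotation is a graph automorphism: RMSD 0
  expect_equal(computeRMSD(rotated, ring, symmetry = TRUE)$rmsd, 0,
               tolerance = 1e-6)
  # without symmetry correction the same rotation scores the full 1.39 A
  expect_gt(computeRMSD(rotated, ring, symmetry = FALSE)$rmsd, 1)
})

test_that("pose minimization relaxes distorted geometry toward equilibrium", {
  # ethane with its C-C bond stretched to 1.9 A
  cmp <- quboDock:::.idealAlkane(2)
  xyz <- coordMatrix(cmp)
  b <- bondTable(cmp)
  cc <- which(atomTable(cmp)$elem == "C")
  d0 <- xyz[cc[2], ] - xyz[cc[1], ]
  stretch <- (1.9 / sqrt(sum(d0^2)) - 1) * d0
  # move the second CH3 rigidly away
  second <- c(cc[2], b$a2[b$a1 == cc[2] & b$a2 > 2])
  xyz[second, ] <- translatePose(xyz[second, , drop = FALSE], stretch)
  cmp@coords <- xyz
  bondLen <- function(m) {
    x <- coordMatrix(m)
    sqrt(sum((x[cc[1], ] - x[cc[2], ])^2))
  }
  expect_equal(bondLen(cmp), 1.9, tolerance = 1e-6)
  minimized <- minimizePose(cmp, steps = 200)
  expect_lt(bondLen(minimized), 1.7)

  # an already relaxed structure barely moves
  again <- minimizePose(minimized, steps = 200)
  expect_lt(abs(bondLen(again) - bondLen(minimized)), 0.05)
})
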