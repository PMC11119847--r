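# Hamiltonian assembly as a QUBO and its two evaluation routes.

test_that("the hand-expanded two-fragment example evaluates to H = -8", {
  q <- quboFromTerms(dG = c(-1, -2), groups = list(1L, 2L),
                     terms = data.frame(i = 1L, j = 2L, clash = 0L,
                                        conn = -1L))
  bd <- evalHamiltonian(q, c(1, 1))
  expect_equal(bd$H1, -3)
  expect_equal(bd$H2, 0)
  expect_equal(bd$H3, -1)
  expect_equal(bd$H4, 0)
  expect_equal(bd$H, -8)
  expect_equal(quboEnergy(q, c(1, 1)), -8)
})

test_that("the all-zeros selection costs the constraint offset D*|F|/2", {
  set.seed(3)
  q4 <- randomQuboInstance(K = 4)
  expect_equal(quboOffset(q4), 50)  # D/2 per fragment, D = 25
  bd <- evalHamiltonian(q4, rep(0, nVariables(q4)))
  expect_equal(bd$H, 4 * 25 / 2)   # 50 for 4 fragments at D = 25
  expect_equal(bd$H1 + bd$H2 + bd$H3, 0)

  # and an empty instance is the empty sum
  q0 <- quboFromTerms(dG = numeric(0), groups = list(), terms = NULL)
  expect_equal(nVariables(q0), 0L)
  expect_equal(quboOffset(q0), 0)
  expect_equal(evalHamiltonian(q0, integer(0))$H, 0)
})

test_that("constraint term follows its closed form", {
  # 3 fragments x 2 placements
  set.seed(9)
  q <- quboFromTerms(dG = rep(-1, 6),
                     groups = list(1:2, 3:4, 5:6), terms = NULL)
  # one per fragment: H4 = 0
  expect_equal(evalHamiltonian(q, c(1, 0, 0, 1, 1, 0))$H4, 0)
  # both placements of one fragment: (2-1)^2 / 2 = 0.5
  expect_equal(evalHamiltonian(q, c(1, 1, 0, 1, 1, 0))$H4, 0.5)
  # general: H4 = 1/2 sum (m_k - 1)^2
  expect_equal(evalHamiltonian(q, c(1, 1, 0, 0, 1, 1))$H4,
               0.5 * ((2 - 1)^2 + (0 - 1)^2 + (2 - 1)^2))
})

test_that("matrix and direct evaluation agree on random instances", {
  set.seed(17)
  maxRel <- 0
  for (it in 1:60) {
    q <- randomQuboInstance(K = sample(2:4, 1), mMax = 4)
    for (v in 1:20) {
      x <- randomBinary(nVariables(q))
      a <- evalHamiltonian(q, x)$H
      b <- quboEnergy(q, x)
      maxRel <- max(maxRel, abs(a - b) / max(1, abs(a)))
    }
  }
  expect_lt(maxRel, 1e-9)
})

test_that("selected clash/conn pairs shift H by exactly B and C", {
  q <- quboFromTerms(dG = c(-1, -1, -1), groups = list(1L, 2L, 3L),
                     terms = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                                        clash = c(1L, 0L),
                                        conn = c(0L, -1L)))
  base <- evalHamiltonian(q, c(1, 0, 0))$H
  withClash <- evalHamiltonian(q, c(1, 1, 0))$H
  withConn <- evalHamiltonian(q, c(1, 0, 1))$H
  B <- quboWeights(q)[["B"]]; C <- quboWeights(q)[["C"]]
  D <- quboWeights(q)[["D"]]
  # selecting placement 2 adds its dG (-1), removes one empty-group D/2
  # penalty ((1-1)^2 vs (0-1)^2), and adds the clash penalty B
  expect_equal(withClash - base, -1 - D / 2 + B)
  expect_equal(withConn - base, -1 - D / 2 - C)
})

test_that("scaling all weights scales H and preserves the argmin", {
  set.seed(31)
  q1 <- randomQuboInstance(K = 3, mMax = 3)
  w2 <- quboWeights(q1) * 3
  q2 <- quboFromTerms(dG = q1@dG, groups = fragmentGroups(q1),
                      terms = q1@terms, weights = w2)
  for (v in 1:10) {
    x <- randomBinary(nVariables(q1))
    expect_equal(3 * evalHamiltonian(q1, x)$H, evalHamiltonian(q2, x)$H,
                 tolerance = 1e-12)
  }
  b1 <- bruteForce(q1, top = 1)
  b2 <- bruteForce(q2, top = 1)
  expect_equal(solutionMatrix(b1)[1, ], solutionMatrix(b2)[1, ])
})

test_that("exports round-trip through all three formats", {
  set.seed(41)
  q <- randomQuboInstance(K = 3, mMax = 2)
  for (fmt in c("json", "qbsolv", "dense")) {
    f <- tempfile()
    exportQUBO(q, f, fmt)
    back <- readQUBO(f, fmt)
    expect_equal(nVariables(back), nVariables(q))
    expect_equal(quboOffset(back), quboOffset(q))
    expect_equal(linearTerms(back), linearTerms(q))
    expect_equal(quadraticTerms(back)$value, quadraticTerms(q)$value)
    expect_equal(quadraticTerms(back)$i, quadraticTerms(q)$i)
  }
  # JSON preserves full provenance: energies agree on random vectors
  f <- tempfile()
  exportQUBO(q, f, "json")
  back <- readQUBO(f, "json")
  for (v in 1:5) {
    x <- randomBinary(nVariables(q))
    expect_equal(evalHamiltonian(back, x)$H, evalHamiltonian(q, x)$H)
  }

  # equal-sized groups survive the JSON round trip as a list (not
  # collapsed into a matrix)
  qeq <- quboFromTerms(dG = rep(-1, 6), groups = list(1:2, 3:4, 5:6),
                       terms = NULL)
  feq <- tempfile()
  exportQUBO(qeq, feq, "json")
  expect_equal(fragmentGroups(readQUBO(feq, "json")),
               lapply(list(1:2, 3:4, 5:6), as.integer))

  # the two-variable example has 2 linear entries and 1 coupler
  q2 <- quboFromTerms(dG = c(-1, -2), groups = list(1L, 2L),
                      terms = data.frame(i = 1L, j = 2L, clash = 0L,
                                         conn = -1L))
  f2 <- tempfile()
  exportQUBO(q2, f2, "qbsolv")
  lines <- grep("^[0-9]", readLines(f2), value = TRUE)
  fields <- do.call(rbind, strsplit(lines, "\\s+"))
  expect_equal(sum(fields[, 1] == fields[, 2]), 2)
  expect_equal(sum(fields[, 1] != fields[, 2]), 1)

  # an empty instance exports and re-imports as a valid empty file
  q0 <- quboFromTerms(dG = numeric(0), groups = list(), terms = NULL)
  f0 <- tempfile()
  exportQUBO(q0, f0, "json")
  expect_equal(nVariables(readQUBO(f0, "json")), 0L)
})

test_that("selection vectors are validated", {
  q <- quboFromTerms(dG = c(-1, -2), groups = list(1L, 2L), terms = NULL)
  expect_error(evalHamiltonian(q, c(1, 0, 1)), "length")
  expect_error(evalHamiltonian(q, c(2, 0)), "binary")
})
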