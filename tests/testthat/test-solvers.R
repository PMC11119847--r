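# Brute-force oracle, simulated annealing and the validity filter.

test_that("brute force solves the hand-derived examples exactly", {
  # two fragments, one placement each, connected: argmin (1,1), H = -8
  q <- quboFromTerms(dG = c(-1, -2), groups = list(1L, 2L),
                     terms = data.frame(i = 1L, j = 2L, clash = 0L,
                                        conn = -1L))
  pool <- bruteForce(q)
  expect_equal(nrow(solutionMatrix(pool)), 4)   # all 2^2 states
  expect_equal(solutionMatrix(pool)[1, ], c(1L, 1L))
  expect_equal(solutionInfo(pool)$H[1], -8)
  expect_true(!is.unsorted(solutionInfo(pool)$H))

  # one fragment, two placements: selecting both costs the constraint
  q2 <- quboFromTerms(dG = c(-1, -2), groups = list(1:2), terms = NULL)
  pool2 <- bruteForce(q2)
  expect_equal(solutionMatrix(pool2)[1, ], c(0L, 1L))
  expect_equal(solutionInfo(pool2)$H[1], -2)
  # (1,1) evaluates to -3 + 25/2 = 9.5
  both <- which(apply(solutionMatrix(pool2), 1, sum) == 2)
  expect_equal(solutionInfo(pool2)$H[both], 9.5)

  # the empty instance has the single empty solution with H = offset
  q0 <- quboFromTerms(dG = numeric(0), groups = list(), terms = NULL)
  pool0 <- bruteForce(q0)
  expect_equal(nrow(solutionMatrix(pool0)), 1)
  expect_equal(solutionInfo(pool0)$H, 0)

  expect_error(bruteForce(randomQuboInstance(K = 4, mMax = 4), maxVars = 3),
               "limited")
})

test_that("every emitted solution's H matches re-evaluation of its vector", {
  set.seed(23)
  for (it in 1:5) {
    q <- randomQuboInstance(K = 3, mMax = 3)
    pool <- simulatedAnneal(q, restarts = 20, sweeps = 50, seed = it)
    for (r in seq_len(nrow(solutionMatrix(pool)))) {
      expect_equal(solutionInfo(pool)$H[r],
                   evalHamiltonian(q, solutionMatrix(pool)[r, ])$H)
    }
  }
})

test_that("simulated annealing is deterministic per seed and nested in restarts", {
  set.seed(77)
  q <- randomQuboInstance(K = 4, mMax = 4)
  p1 <- simulatedAnneal(q, restarts = 40, sweeps = 60, seed = 5)
  p2 <- simulatedAnneal(q, restarts = 40, sweeps = 60, seed = 5)
  expect_identical(solutionMatrix(p1), solutionMatrix(p2))
  expect_identical(solutionInfo(p1)$H, solutionInfo(p2)$H)

  # zero restarts: empty pool
  p0 <- simulatedAnneal(q, restarts = 0, seed = 5)
  expect_equal(nrow(solutionMatrix(p0)), 0)

  # enlarging the restart budget never worsens the best H (same seed:
  # the first restarts of the longer run replay the shorter run)
  best <- sapply(c(5, 20, 60), function(r)
    solutionInfo(simulatedAnneal(q, restarts = r, sweeps = 60,
                                 seed = 9))$H[1])
  expect_true(all(diff(best) <= 1e-12))
})

test_that("annealing attains the exact optimum on most random planted instances", {
  set.seed(55)
  hits <- 0
  nInst <- 50
  for (it in seq_len(nInst)) {
    q <- randomQuboInstance(K = sample(3:4, 1), mMax = 4)  # n <= 16
    opt <- solutionInfo(bruteForce(q, top = 1))$H[1]
    got <- solutionInfo(simulatedAnneal(q, restarts = 100, sweeps = 100,
                                        seed = 1000 + it))$H[1]
    expect_gte(got, opt - 1e-9)
    if (abs(got - opt) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / nInst, 0.95)
})

test_that("the postprocess filter keeps exactly the one-per-fragment solutions", {
  set.seed(61)
  q <- randomQuboInstance(K = 3, mMax = 3)
  pool <- bruteForce(q, top = 2^nVariables(q))
  filtered <- postprocessFilter(pool, q)
  m <- solutionMatrix(filtered)
  expect_true(nrow(m) > 0)
  for (S in fragmentGroups(q)) {
    expect_true(all(rowSums(m[, S, drop = FALSE]) == 1))
  }
  # filter soundness: post-filter pools contain only H4 = 0 vectors
  expect_true(all(solutionInfo(filtered)$H4 == 0))
  # the retained count is the product of the group sizes
  expect_equal(nrow(m),
               prod(vapply(fragmentGroups(q), length, integer(1))))
  expect_equal(attr(filtered, "retainedFraction"),
               nrow(m) / nrow(solutionMatrix(pool)))

  # a solution selecting two placements of a fragment is removed
  q2 <- quboFromTerms(dG = c(-1, -2), groups = list(1:2), terms = NULL)
  pool2 <- bruteForce(q2)
  f2 <- postprocessFilter(pool2, q2)
  expect_true(all(rowSums(solutionMatrix(f2)) == 1))
})

test_that("solution pools are distinct, sorted and annotated", {
  set.seed(71)
  q <- randomQuboInstance(K = 3, mMax = 3)
  pool <- simulatedAnneal(q, restarts = 200, sweeps = 50, seed = 2)
  keys <- apply(solutionMatrix(pool), 1, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(!is.unsorted(solutionInfo(pool)$H))
  w <- quboWeights(q)
  expect_equal(solutionInfo(pool)$H,
               w[["A"]] * solutionInfo(pool)$H1 +
               w[["B"]] * solutionInfo(pool)$H2 +
               w[["C"]] * solutionInfo(pool)$H3 +
               w[["D"]] * solutionInfo(pool)$H4)
})
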