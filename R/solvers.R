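# QUBO solvers: an exhaustive brute-force oracle for small instances, a
# multi-restart simulated-annealing solver collecting many distinct local
# solutions, and the validity postprocessing filter.

# assemble a SolutionPool from raw solver output: dedup by bit vector,
# sort by H then lexicographically, annotate with the term breakdown
.makePool <- function(qubo, X, restart, solver) {
  if (is.null(dim(X))) X <- matrix(X, ncol = qubo@n)
  storage.mode(X) <- "integer"
  if (nrow(X) == 0)
    return(new("SolutionPool",
               X = matrix(integer(0), 0, qubo@n),
               info = data.frame(H = numeric(0), H1 = numeric(0),
                                 H2 = numeric(0), H3 = numeric(0),
                                 H4 = numeric(0), valid = logical(0),
                                 solver = character(0),
                                 restart = integer(0))))
  keys <- apply(X, 1, paste, collapse = "")
  first <- !duplicated(keys)
  X <- X[first, , drop = FALSE]
  restart <- restart[first]
  bd <- lapply(seq_len(nrow(X)), function(r) evalHamiltonian(qubo, X[r, ]))
  H <- vapply(bd, `[[`, numeric(1), "H")
  keys <- keys[first]
  o <- order(H, keys)
  X <- X[o, , drop = FALSE]
  bd <- bd[o]
  info <- data.frame(
    H = vapply(bd, `[[`, numeric(1), "H"),
    H1 = vapply(bd, `[[`, numeric(1), "H1"),
    H2 = vapply(bd, `[[`, numeric(1), "H2"),
    H3 = vapply(bd, `[[`, numeric(1), "H3"),
    H4 = vapply(bd, `[[`, numeric(1), "H4"),
    valid = vapply(seq_len(nrow(X)), function(r)
      .isValidSelection(qubo, X[r, ]), logical(1)),
    solver = solver,
    restart = restart[o])
  pool <- new("SolutionPool", X = X, info = info)
  validObject(pool)
  pool
}

.isValidSelection <- function(qubo, x) {
  all(vapply(qubo@groups, function(S) sum(x[S]) == 1, logical(1)))
}

#' Exhaustive brute-force minimization (ground-truth oracle)
#'
#' Enumerates all 2^n selection vectors with an incremental Gray-code walk
#' and returns the `top` best solutions sorted by H (ties broken
#' lexicographically).  The first pool element is the exact global optimum.
#'
#' @param qubo a [QUBOProblem-class].
#' @param maxVars refuse instances larger than this (default 25).
#' @param top pool size to retain (default 1000).
#' @return a [SolutionPool-class].
#' @export
bruteForce <- function(qubo, maxVars = 25L, top = 1000L) {
  if (qubo@n > maxVars)
    stop("instance has ", qubo@n, " variables; brute force is limited to ",
         maxVars, " (raise 'maxVars' explicitly if you mean it)")
  if (qubo@n == 0L)
    return(.makePool(qubo, matrix(integer(0), 1, 0), 1L, "brute"))
  res <- .bruteForceCpp(qubo@h, .denseJ(qubo), qubo@offset, as.integer(top))
  .makePool(qubo, res$X, rep(1L, nrow(res$X)), "brute")
}

#' Multi-restart simulated annealing
#'
#' Independent restarts of single-bit-flip Metropolis annealing under a
#' geometric temperature schedule, each followed by a zero-temperature
#' quench; the final state of every restart enters the pool.  The initial
#' temperature defaults to an upper bound on the energy change of any
#' single flip, and the final temperature to 1e-3 of the initial.  Fully
#' reproducible for a fixed seed; with a time budget set, the number of
#' completed restarts may depend on machine speed.
#'
#' @param qubo a [QUBOProblem-class].
#' @param restarts number of independent restarts (default 100).
#' @param sweeps temperature steps per restart; each sweep visits all
#'   variables once (default 100).
#' @param seed optional integer seed (applied with [set.seed()]).
#' @param T0,Tend initial/final temperature (defaults: single-flip bound,
#'   1e-3 * T0).
#' @param timeBudget optional wall-clock budget in seconds; restarts stop
#'   when exceeded.
#' @return a [SolutionPool-class].
#' @export
simulatedAnneal <- function(qubo, restarts = 100L, sweeps = 100L,
                            seed = NULL, T0 = NULL, Tend = NULL,
                            timeBudget = 0) {
  if (restarts < 0 || sweeps <= 0) stop("restarts/sweeps must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (restarts == 0L || qubo@n == 0L) {
    X <- if (qubo@n == 0L && restarts > 0L)
      matrix(integer(0), 1, 0) else matrix(integer(0), 0, qubo@n)
    return(.makePool(qubo, X, rep(1L, nrow(X)), "sa"))
  }
  if (is.null(T0)) {
    Jabs <- abs(.denseJ(qubo))
    T0 <- max(abs(qubo@h) + rowSums(Jabs), 1e-6)
  }
  if (is.null(Tend)) Tend <- max(1e-3 * T0, 1e-9)
  res <- .simulatedAnnealCpp(qubo@h, .denseJ(qubo), qubo@offset,
                             as.integer(restarts), as.integer(sweeps),
                             T0, Tend, as.numeric(timeBudget))
  .makePool(qubo, res$X, res$restart, "sa")
}

#' Filter a solution pool down to valid selections
#'
#' Retains exactly the solutions selecting a single placement per fragment
#' (sum over every fragment group equals 1, i.e. H4 = 0).  The retained
#' fraction is attached as attribute `"retainedFraction"`.
#'
#' @param pool a [SolutionPool-class].
#' @param qubo the [QUBOProblem-class] the pool belongs to (provides the
#'   fragment groups).
#' @return the filtered [SolutionPool-class].
#' @export
postprocessFilter <- function(pool, qubo) {
  n0 <- nrow(pool@X)
  keep <- vapply(seq_len(n0), function(r)
    .isValidSelection(qubo, pool@X[r, ]), logical(1))
  out <- new("SolutionPool", X = pool@X[keep, , drop = FALSE],
             info = pool@info[keep, , drop = FALSE])
  rownames(out@info) <- NULL
  attr(out, "retainedFraction") <- if (n0 > 0) mean(keep) else NA_real_
  validObject(out)
  out
}

#' Write a solution pool as TSV (rank, energies, validity, bitstring)
#'
#' @param pool a [SolutionPool-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSolutionsTSV <- function(pool, file) {
  df <- cbind(data.frame(rank = seq_len(nrow(pool@X))), pool@info,
              data.frame(bitstring = apply(pool@X, 1, paste, collapse = "")))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
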