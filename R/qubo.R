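# Assembly and evaluation of the four-term docking Hamiltonian
#
#   H = A*H1 + B*H2 + C*H3 + D*H4
#
# H1 = sum_i dG_i x_i                       (placement fitness)
# H2 = sum_{i<j} clash(i,j) x_i x_j         (steric clash penalty)
# H3 = sum_{i<j} conn(i,j) x_i x_j          (covalent-bond reward)
# H4 = 1/2 sum_k (sum_{i in S_k} x_i - 1)^2
#      + 1/2 sum_i x_i (1 - x_i)            (one placement per fragment)
#
# The pairwise sums run over unordered pairs i < j with one contribution
# per pair; any double-counting convention is absorbable into B and C.
# The second H4 term vanishes identically for binary x and contributes
# nothing to the QUBO coefficients; it is kept in the direct evaluator for
# fidelity to the constraint's written form.

#' Default Hamiltonian weights
#'
#' @param A,B,C,D non-negative term weights; defaults (1, 5, 5, 25).
#' @return named numeric vector.
#' @export
hamiltonianWeights <- function(A = 1, B = 5, C = 5, D = 25) {
  w <- c(A = A, B = B, C = C, D = D)
  if (any(w < 0)) stop("weights must be non-negative")
  w
}

#' Build the QUBO from placements and binarized pair terms
#'
#' Expands the Hamiltonian into linear coefficients, quadratic coefficients
#' over unordered pairs and a tracked constant offset, using the binary
#' reduction x_i^2 = x_i.  Per fragment group S_k the constraint term
#' contributes -D/2 to each linear coefficient, +D to each in-group pair
#' and +D/2 to the offset.
#'
#' @param placements a [PlacementSet-class].
#' @param terms data.frame of binarized pair terms (`i`, `j`, `clash`,
#'   `conn`), e.g. from [pairTerms()].
#' @param weights named numeric (A, B, C, D), see [hamiltonianWeights()].
#' @return a [QUBOProblem-class].
#' @export
buildQUBO <- function(placements, terms,
                      weights = hamiltonianWeights()) {
  tb <- placements@table
  quboFromTerms(dG = tb$score, groups = fragmentGroups(placements),
                terms = terms, weights = weights,
                placementIds = tb$id, fragmentIds = tb$fragment)
}

#' Build a QUBO problem from raw ingredients
#'
#' Lower-level constructor behind [buildQUBO()], also used by the instance
#' generator, file import and tests: no [PlacementSet-class] required.
#'
#' @param dG numeric scores per variable.
#' @param groups list mapping fragment -> variable ids; empty groups
#'   (fragments without any placement) are allowed and contribute their
#'   constant D/2 to the offset.
#' @param terms data.frame (`i`, `j`, `clash`, `conn`) or NULL.
#' @param weights named numeric (A, B, C, D).
#' @param placementIds,fragmentIds optional provenance for the variable map.
#' @return a [QUBOProblem-class].
#' @export
quboFromTerms <- function(dG, groups, terms,
                          weights = hamiltonianWeights(),
                          placementIds = NULL, fragmentIds = NULL) {
  n <- length(dG)
  groups <- lapply(groups, as.integer)
  gv <- unlist(groups)
  if (n > 0 && (!setequal(gv, seq_len(n)) || anyDuplicated(gv)))
    stop("fragment groups must partition the variables 1..n")
  A <- weights[["A"]]; B <- weights[["B"]]
  C <- weights[["C"]]; D <- weights[["D"]]

  h <- A * as.numeric(dG)
  offset <- 0

  Jmap <- new.env(hash = TRUE)
  addJ <- function(i, j, v) {
    key <- sprintf("%09d %09d", min(i, j), max(i, j))
    cur <- if (is.null(Jmap[[key]])) 0 else Jmap[[key]]
    Jmap[[key]] <- cur + v
  }

  if (!is.null(terms) && nrow(terms)) {
    if (any(terms$i == terms$j))
      stop("pair terms must reference two distinct placements")
    if (any(terms$i < 1 | terms$j < 1 | terms$i > n | terms$j > n))
      stop("pair term references an unknown placement")
    for (r in seq_len(nrow(terms))) {
      v <- B * terms$clash[r] + C * terms$conn[r]
      if (v != 0) addJ(terms$i[r], terms$j[r], v)
    }
  }

  for (S in groups) {
    offset <- offset + D / 2
    if (length(S)) h[S] <- h[S] - D / 2
    if (length(S) > 1) {
      for (a in seq_len(length(S) - 1))
        for (b in (a + 1):length(S))
          addJ(S[a], S[b], D)
    }
  }

  keys <- sort(ls(Jmap))
  if (length(keys)) {
    ij <- do.call(rbind, lapply(keys, function(k)
      as.integer(strsplit(k, " ")[[1]])))
    J <- data.frame(i = ij[, 1], j = ij[, 2],
                    value = vapply(keys, function(k) Jmap[[k]], numeric(1)))
    rownames(J) <- NULL
  } else {
    J <- data.frame(i = integer(0), j = integer(0), value = numeric(0))
  }

  terms2 <- if (is.null(terms) || !nrow(terms)) {
    data.frame(i = integer(0), j = integer(0), clash = integer(0),
               conn = integer(0))
  } else {
    data.frame(i = pmin(terms$i, terms$j), j = pmax(terms$i, terms$j),
               clash = as.integer(terms$clash), conn = as.integer(terms$conn))
  }

  if (is.null(placementIds)) placementIds <- seq_len(n)
  if (is.null(fragmentIds)) {
    fragmentIds <- integer(n)
    for (k in seq_along(groups)) fragmentIds[groups[[k]]] <- k
  }

  obj <- new("QUBOProblem", n = as.integer(n), h = h, J = J,
             offset = offset, dG = as.numeric(dG), terms = terms2,
             groups = groups, weights = weights,
             map = data.frame(variable = seq_len(n),
                              placement = as.integer(placementIds),
                              fragment = as.integer(fragmentIds)))
  validObject(obj)
  obj
}

#' Evaluate the Hamiltonian term-by-term for a selection vector
#'
#' Computes H1..H4 directly from their defining sums (without the binary
#' reduction) and the weighted total.  This is the reference route; it must
#' agree with the reduced QUBO evaluation [quboEnergy()].
#'
#' @param qubo a [QUBOProblem-class].
#' @param x integer 0/1 vector of length n.
#' @return list with `H1`, `H2`, `H3`, `H4`, `H`.
#' @export
evalHamiltonian <- function(qubo, x) {
  if (length(x) != qubo@n) stop("selection vector has wrong length")
  if (!all(x %in% c(0, 1))) stop("selection vector must be binary")
  x <- as.numeric(x)
  H1 <- sum(qubo@dG * x)
  H2 <- 0; H3 <- 0
  if (nrow(qubo@terms)) {
    xx <- x[qubo@terms$i] * x[qubo@terms$j]
    H2 <- sum(qubo@terms$clash * xx)
    H3 <- sum(qubo@terms$conn * xx)
  }
  H4 <- 0.5 * sum(vapply(qubo@groups, function(S)
    (sum(x[S]) - 1)^2, numeric(1))) + 0.5 * sum(x * (1 - x))
  w <- qubo@weights
  list(H1 = H1, H2 = H2, H3 = H3, H4 = H4,
       H = w[["A"]] * H1 + w[["B"]] * H2 + w[["C"]] * H3 + w[["D"]] * H4)
}

#' Evaluate the reduced QUBO form for a selection vector
#'
#' offset + sum_i h_i x_i + sum_{i<j} J_ij x_i x_j.  Agrees with
#' [evalHamiltonian()]'s total for binary input.
#'
#' @param qubo a [QUBOProblem-class].
#' @param x integer 0/1 vector.
#' @return numeric H.
#' @export
quboEnergy <- function(qubo, x) {
  if (length(x) != qubo@n) stop("selection vector has wrong length")
  x <- as.numeric(x)
  e <- qubo@offset + sum(qubo@h * x)
  if (nrow(qubo@J))
    e <- e + sum(qubo@J$value * x[qubo@J$i] * x[qubo@J$j])
  e
}

# dense symmetric coupling matrix (for the compiled solvers)
.denseJ <- function(qubo) {
  M <- matrix(0, qubo@n, qubo@n)
  if (nrow(qubo@J)) {
    for (r in seq_len(nrow(qubo@J))) {
      M[qubo@J$i[r], qubo@J$j[r]] <- qubo@J$value[r]
      M[qubo@J$j[r], qubo@J$i[r]] <- qubo@J$value[r]
    }
  }
  M
}

#' Export a QUBO instance to a file
#'
#' Formats: `"json"` (coefficients, offset, groups, variable map; lossless),
#' `"qbsolv"` (qbsolv-style text with 0-based variable indices and the
#' offset on a comment line) and `"dense"` (dense symmetric matrix text
#' with linear terms on the diagonal).  JSON round-trips exactly through
#' [readQUBO()].
#'
#' @param qubo a [QUBOProblem-class].
#' @param file output path.
#' @param format one of "json", "qbsolv", "dense".
#' @return the path, invisibly.
#' @export
exportQUBO <- function(qubo, file, format = c("json", "qbsolv", "dense")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      n = qubo@n, h = qubo@h,
      J = qubo@J, offset = qubo@offset, dG = qubo@dG,
      terms = qubo@terms,
      groups = lapply(qubo@groups, as.integer),
      weights = as.list(qubo@weights),
      map = qubo@map)
    jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  } else if (format == "qbsolv") {
    lines <- c(sprintf("c quboDock QUBO export, offset %.17g", qubo@offset),
               sprintf("p qubo 0 %d %d %d", qubo@n,
                       sum(qubo@h != 0), nrow(qubo@J)))
    for (i in which(qubo@h != 0))
      lines <- c(lines, sprintf("%d %d %.17g", i - 1L, i - 1L, qubo@h[i]))
    for (r in seq_len(nrow(qubo@J)))
      lines <- c(lines, sprintf("%d %d %.17g", qubo@J$i[r] - 1L,
                                qubo@J$j[r] - 1L, qubo@J$value[r]))
    writeLines(lines, file)
  } else {
    M <- .denseJ(qubo)
    diag(M) <- qubo@h
    lines <- c(sprintf("# quboDock dense QUBO, n %d, offset %.17g",
                       qubo@n, qubo@offset),
               vapply(seq_len(qubo@n), function(i)
                 paste(sprintf("%.17g", M[i, ]), collapse = " "),
                 character(1)))
    writeLines(lines, file)
  }
  invisible(file)
}

#' Read a QUBO instance back from a file
#'
#' @param file path written by [exportQUBO()].
#' @param format one of "json", "qbsolv", "dense".
#' @return a [QUBOProblem-class]; qbsolv/dense imports carry coefficients
#'   and offset only (no pair-term/group provenance), with every variable
#'   placed in its own group.
#' @export
readQUBO <- function(file, format = c("json", "qbsolv", "dense")) {
  format <- match.arg(format)
  if (format == "json") {
    p <- jsonlite::read_json(file, simplifyVector = TRUE)
    J <- as.data.frame(p$J)
    if (!nrow(J)) J <- data.frame(i = integer(0), j = integer(0),
                                  value = numeric(0))
    terms <- as.data.frame(p$terms)
    if (!nrow(terms)) terms <- data.frame(i = integer(0), j = integer(0),
                                          clash = integer(0),
                                          conn = integer(0))
    groups <- p$groups
    if (is.matrix(groups))   # equal-length groups simplify to a matrix
      groups <- lapply(seq_len(nrow(groups)), function(r) groups[r, ])
    obj <- new("QUBOProblem", n = as.integer(p$n),
               h = as.numeric(p$h), J = J, offset = as.numeric(p$offset),
               dG = as.numeric(p$dG), terms = terms,
               groups = lapply(groups, as.integer),
               weights = unlist(p$weights),
               map = as.data.frame(p$map))
    validObject(obj)
    return(obj)
  }
  lines <- readLines(file)
  if (format == "qbsolv") {
    off <- 0
    cmt <- grep("^c .*offset", lines, value = TRUE)
    if (length(cmt)) off <- as.numeric(sub(".*offset ", "", cmt[1]))
    pl <- strsplit(trimws(grep("^p ", lines, value = TRUE)[1]), "\\s+")[[1]]
    n <- as.integer(pl[4])
    h <- numeric(n)
    J <- data.frame(i = integer(0), j = integer(0), value = numeric(0))
    for (ln in grep("^[0-9]", lines, value = TRUE)) {
      fl <- strsplit(trimws(ln), "\\s+")[[1]]
      i <- as.integer(fl[1]) + 1L; j <- as.integer(fl[2]) + 1L
      v <- as.numeric(fl[3])
      if (i == j) h[i] <- v else
        J <- rbind(J, data.frame(i = min(i, j), j = max(i, j), value = v))
    }
  } else {
    off <- as.numeric(sub(".*offset ", "", lines[1]))
    n <- as.integer(sub(".*n (\\d+),.*", "\\1", lines[1]))
    M <- do.call(rbind, lapply(lines[-1], function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
    h <- if (n > 0) diag(M) else numeric(0)
    J <- data.frame(i = integer(0), j = integer(0), value = numeric(0))
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (M[i, j] != 0)
          J <- rbind(J, data.frame(i = i, j = j, value = M[i, j]))
    }
  }
  if (nrow(J)) { J <- J[order(J$i, J$j), , drop = FALSE]; rownames(J) <- NULL }
  obj <- new("QUBOProblem", n = n, h = h, J = J, offset = off,
             dG = h, terms = data.frame(i = integer(0), j = integer(0),
                                        clash = integer(0), conn = integer(0)),
             groups = as.list(seq_len(n)),
             weights = hamiltonianWeights(),
             map = data.frame(variable = seq_len(n),
                              placement = seq_len(n),
                              fragment = seq_len(n)))
  validObject(obj)
  obj
}
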