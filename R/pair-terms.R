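# Pairwise placement relations: UFF interaction energies EB/ENB, their
# binarization into clash(i,j) in {0,1} and conn(i,j) in {-1,0}, a purely
# geometric alternative, and a distance prefilter that skips force-field
# work for far-apart pairs.
#
# Energy convention: both EB and ENB subtract the internal UFF energy of
# each isolated capped fragment at identical coordinates, so they are pure
# interaction/distortion energies and a distant pair evaluates to ~0.

.KJ_PER_KCAL <- 4.184

# build a ChemmineR SDF object from raw atom/bond arrays (the two-fragment
# systems evaluated here may be disconnected, which Compound forbids)
.rawSDF <- function(elem, xyz, a1, a2, ord, name = "sys") {
  n <- length(elem); m <- length(a1)
  # 4 decimals keep the fixed-width V2000 atom block aligned
  ab <- cbind(round(xyz, 4), matrix(0L, n, 12))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(elem, seq_len(n), sep = "_")
  bb <- if (m > 0) cbind(a1, a2, ord, matrix(0L, m, 4)) else
    matrix(integer(0), 0, 7)
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- as.character(seq_len(m))
  header <- c(Molecule_Name = name, Source = "  quboDock          3D",
              Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, m))
  new("SDF", header = header, atomblock = ab, bondblock = bb,
      datablock = character(0))
}

# UFF energies (kcal/mol) of a list of systems.  One obenergy invocation
# per record: OpenBabel's force-field state is not reliably reset between
# the records of a multi-molecule file, so batching within one call
# contaminates the energies.
.uffEnergies <- function(sdfList) {
  if (!length(sdfList)) return(numeric(0))
  .obCheck()
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  vapply(sdfList, function(sdf) {
    ChemmineR::write.SDF(new("SDFset", SDF = list(sdf), ID = "m"),
                         file = f, cid = TRUE)
    out <- suppressWarnings(system2("obenergy", c("-ff", "UFF", f),
                                    stdout = TRUE, stderr = FALSE))
    line <- grep("^TOTAL ENERGY", out, value = TRUE)
    if (length(line) != 1L)
      stop("force-field evaluation failed for a pair system ",
           "(check atom parameterization)")
    val <- as.numeric(sub("^TOTAL ENERGY\\s*=\\s*([-0-9.eE+]+).*", "\\1",
                          line))
    if (grepl("kJ/mol", line)) val <- val / .KJ_PER_KCAL
    val
  }, numeric(1))
}

#' UFF energy of a single placed fragment or compound (kcal/mol)
#'
#' @param compound a [Compound-class] with 3D coordinates.
#' @return energy in kcal/mol.
#' @export
uffEnergy <- function(compound) {
  if (is.null(compound@coords)) stop("3D coordinates required")
  .uffEnergies(list(.compoundToSDF(compound)))
}

# the dimer system of two placements, no bond added
.dimerSDF <- function(frag1, xyz1, frag2, xyz2) {
  n1 <- nrow(frag1@compound@atoms)
  b1 <- frag1@compound@bonds; b2 <- frag2@compound@bonds
  .rawSDF(c(frag1@compound@atoms$elem, frag2@compound@atoms$elem),
          rbind(xyz1, xyz2),
          c(b1$a1, b2$a1 + n1), c(b1$a2, b2$a2 + n1),
          c(b1$order, b2$order))
}

# the merged single molecule: caps at the formed bond removed, bond added
.mergedSDF <- function(frag1, xyz1, frag2, xyz2, att) {
  # att: row of frag1's attachments with partner == frag2 id
  cap1 <- att$cap; heavy1 <- att$heavy
  att2 <- frag2@attachments[frag2@attachments$partner == frag1@id &
                            frag2@attachments$partnerHeavy == heavy1, ]
  if (nrow(att2) != 1L)
    stop("attachment records between fragments ", frag1@id, " and ",
         frag2@id, " are not reciprocal")
  cap2 <- att2$cap; heavy2 <- att2$heavy
  n1 <- nrow(frag1@compound@atoms); n2 <- nrow(frag2@compound@atoms)
  keep1 <- setdiff(seq_len(n1), cap1); keep2 <- setdiff(seq_len(n2), cap2)
  map1 <- match(seq_len(n1), keep1)
  map2 <- match(seq_len(n2), keep2) + length(keep1)
  b1 <- frag1@compound@bonds; b2 <- frag2@compound@bonds
  s1 <- b1$a1 != cap1 & b1$a2 != cap1
  s2 <- b2$a1 != cap2 & b2$a2 != cap2
  .rawSDF(c(frag1@compound@atoms$elem[keep1], frag2@compound@atoms$elem[keep2]),
          rbind(xyz1[keep1, , drop = FALSE], xyz2[keep2, , drop = FALSE]),
          c(map1[b1$a1[s1]], map2[b2$a1[s2]], map1[heavy1]),
          c(map1[b1$a2[s1]], map2[b2$a2[s2]], map2[heavy2]),
          c(b1$order[s1], b2$order[s2], 1L))
}

#' Non-bonded interaction energy ENB between two placements
#'
#' UFF energy of the two placed capped fragments treated as one system with
#' no added bond, minus the internal energy of each fragment alone at the
#' same coordinates (kcal/mol).
#'
#' @param frag1,frag2 [Fragment-class] objects (different fragments).
#' @param xyz1,xyz2 coordinate matrices in fragment atom order.
#' @return ENB in kcal/mol.
#' @export
computeENB <- function(frag1, xyz1, frag2, xyz2) {
  if (frag1@id == frag2@id) stop("ENB is defined for different fragments only")
  e <- .uffEnergies(list(
    .dimerSDF(frag1, xyz1, frag2, xyz2),
    .rawSDF(frag1@compound@atoms$elem, xyz1, frag1@compound@bonds$a1,
            frag1@compound@bonds$a2, frag1@compound@bonds$order),
    .rawSDF(frag2@compound@atoms$elem, xyz2, frag2@compound@bonds$a1,
            frag2@compound@bonds$a2, frag2@compound@bonds$order)))
  e[1] - e[2] - e[3]
}

#' Bonded interaction energy EB between two placements
#'
#' Builds the merged molecule (the two cap hydrogens at the attachment
#' removed, the covalent bond added) at fixed coordinates and returns its
#' UFF energy minus the internal energies of the two isolated capped
#' fragments (kcal/mol).  Includes the bond-stretch, angle and dihedral
#' distortion created by the merge.
#'
#' @param frag1,frag2 [Fragment-class] objects bonded in the parent.
#' @param xyz1,xyz2 coordinate matrices in fragment atom order.
#' @return EB in kcal/mol.
#' @export
computeEB <- function(frag1, xyz1, frag2, xyz2) {
  att <- frag1@attachments[frag1@attachments$partner == frag2@id, ]
  if (nrow(att) == 0L)
    stop("fragments ", frag1@id, " and ", frag2@id,
         " are not bonded in the parent compound")
  att <- att[1, ]
  e <- .uffEnergies(list(
    .mergedSDF(frag1, xyz1, frag2, xyz2, att),
    .rawSDF(frag1@compound@atoms$elem, xyz1, frag1@compound@bonds$a1,
            frag1@compound@bonds$a2, frag1@compound@bonds$order),
    .rawSDF(frag2@compound@atoms$elem, xyz2, frag2@compound@bonds$a1,
            frag2@compound@bonds$a2, frag2@compound@bonds$order)))
  e[1] - e[2] - e[3]
}

#' Binarize pair energies into clash/conn terms
#'
#' Applies the two rules in order: first `conn(i,j) = -1` if the fragments
#' are covalently bonded in the parent and `EB <= thE`, else 0; then
#' `clash(i,j) = 1` if `conn(i,j) = 0` and `ENB > thE`, else 0.  The two
#' indicators are mutually exclusive by construction.
#'
#' @param pairs data.frame with columns `bonded` (logical), `EB`
#'   (kcal/mol, NA when not bonded) and `ENB` (kcal/mol).
#' @param thE energy tolerance (kcal/mol, default 500; must be positive).
#' @return the input with columns `conn` and `clash` appended.
#' @examples
#' binarizePairEnergies(data.frame(bonded = TRUE, EB = -2, ENB = 900))
#' @export
binarizePairEnergies <- function(pairs, thE = 500) {
  if (thE <= 0) stop("energy tolerance thE must be positive")
  conn <- ifelse(pairs$bonded & !is.na(pairs$EB) & pairs$EB <= thE, -1L, 0L)
  clash <- ifelse(conn == 0L & pairs$ENB > thE, 1L, 0L)
  pairs$conn <- conn
  pairs$clash <- clash
  pairs
}

# minimum inter-fragment heavy-atom distance
.minHeavyDist <- function(frag1, xyz1, frag2, xyz2) {
  h1 <- which(frag1@compound@atoms$elem != "H")
  h2 <- which(frag2@compound@atoms$elem != "H")
  x1 <- xyz1[h1, , drop = FALSE]; x2 <- xyz2[h2, , drop = FALSE]
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * (x1 %*% t(x2))
  sqrt(max(min(d2), 0))
}

# attachment heavy-atom distance for a bonded fragment pair (NA if unbonded)
.attachmentDistance <- function(frag1, xyz1, frag2, xyz2) {
  att <- frag1@attachments[frag1@attachments$partner == frag2@id, ]
  if (nrow(att) == 0L) return(NA_real_)
  p <- xyz1[att$heavy[1], ]
  q <- xyz2[att$partnerHeavy[1], ]
  sqrt(sum((p - q)^2))
}

#' Geometric clash/conn terms for one placement pair
#'
#' Distance-based alternative to the force-field route: `conn = -1` when
#' the fragments are bonded in the parent and the attachment heavy atoms
#' lie inside `bondWindow`; otherwise `clash = 1` when the minimum
#' inter-fragment heavy-atom distance is below `clashDistance`.
#'
#' @param frag1,frag2 [Fragment-class] objects (different fragments).
#' @param xyz1,xyz2 coordinate matrices.
#' @param clashDistance Angstrom (default 2.0).
#' @param bondWindow numeric length-2 interval in Angstrom (default
#'   c(1.2, 2.0)).
#' @return list with elements `clash` and `conn`.
#' @export
geometricPairTerms <- function(frag1, xyz1, frag2, xyz2,
                               clashDistance = 2.0,
                               bondWindow = c(1.2, 2.0)) {
  if (clashDistance <= 0 || any(bondWindow <= 0))
    stop("geometric thresholds must be positive")
  ad <- .attachmentDistance(frag1, xyz1, frag2, xyz2)
  conn <- if (!is.na(ad) && ad >= bondWindow[1] && ad <= bondWindow[2])
    -1L else 0L
  clash <- if (conn == 0L &&
               .minHeavyDist(frag1, xyz1, frag2, xyz2) < clashDistance)
    1L else 0L
  list(clash = clash, conn = conn)
}

#' Distance prefilter for a placement pair
#'
#' Far-apart pairs have clash = 0 and conn = 0 without any force-field
#' evaluation: when the minimum inter-fragment heavy-atom distance exceeds
#' `cutoff` and, for bonded fragments, the attachment atoms are too far to
#' bond, the pair is decided immediately.
#'
#' @param frag1,frag2 [Fragment-class] objects.
#' @param xyz1,xyz2 coordinate matrices.
#' @param cutoff Angstrom (default 8).
#' @param maxBondLength attachment distances above this can never form a
#'   bond (default 3 Angstrom, generous against thE).
#' @return list `(decided=, clash=, conn=, connDecided=)`.  `decided = TRUE`
#'   fixes both indicators at 0 with no energy call; `connDecided = TRUE`
#'   alone fixes `conn = 0` (unbondable geometry) while clash still needs
#'   the energy path.
#' @export
pairPrefilter <- function(frag1, xyz1, frag2, xyz2, cutoff = 8,
                          maxBondLength = 3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ad <- .attachmentDistance(frag1, xyz1, frag2, xyz2)
  bonded <- !is.na(ad)
  connDecided <- !bonded || ad > maxBondLength
  if (connDecided && .minHeavyDist(frag1, xyz1, frag2, xyz2) > cutoff)
    return(list(decided = TRUE, clash = 0L, conn = 0L, connDecided = TRUE))
  list(decided = FALSE, clash = NA_integer_,
       conn = if (connDecided) 0L else NA_integer_,
       connDecided = connDecided)
}

#' Compute binarized pair terms for all placement pairs
#'
#' Iterates over all unordered placement pairs (i < j) whose fragments
#' differ, decides distant pairs with [pairPrefilter()] (energy mode), and
#' computes the remaining pairs either through batched UFF energies
#' (`mode = "energy"`) or through the distance rules
#' (`mode = "geometric"`).
#'
#' @param placements a [PlacementSet-class].
#' @param mode "energy" or "geometric".
#' @param thE energy tolerance in kcal/mol (default 500).
#' @param prefilterCutoff Angstrom (default 8); set to Inf to disable the
#'   prefilter.
#' @param clashDistance,bondWindow geometric-mode thresholds.
#' @return data.frame with columns `i`, `j`, `ENB`, `EB`, `clash`, `conn`
#'   (energies NA where the prefilter decided or in geometric mode).
#' @export
pairTerms <- function(placements, mode = c("energy", "geometric"),
                      thE = 500, prefilterCutoff = 8,
                      clashDistance = 2.0, bondWindow = c(1.2, 2.0)) {
  mode <- match.arg(mode)
  tb <- placements@table
  n <- nrow(tb)
  frs <- placements@fragmentation@fragments
  bondedPair <- matrix(FALSE, length(frs), length(frs))
  ib <- placements@fragmentation@bonds
  for (r in seq_len(nrow(ib))) {
    bondedPair[ib$f1[r], ib$f2[r]] <- TRUE
    bondedPair[ib$f2[r], ib$f1[r]] <- TRUE
  }

  out <- data.frame(i = integer(0), j = integer(0), ENB = numeric(0),
                    EB = numeric(0), clash = integer(0), conn = integer(0))
  if (n < 2) return(out)

  pend <- list()   # pairs needing energy evaluation
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fi <- tb$fragment[i]; fj <- tb$fragment[j]
      if (fi == fj) next
      f1 <- frs[[fi]]; f2 <- frs[[fj]]
      x1 <- placements@coords[[i]]; x2 <- placements@coords[[j]]
      if (mode == "geometric") {
        gt <- geometricPairTerms(f1, x1, f2, x2, clashDistance, bondWindow)
        out <- rbind(out, data.frame(i = i, j = j, ENB = NA_real_,
                                     EB = NA_real_, clash = gt$clash,
                                     conn = gt$conn))
        next
      }
      pf <- if (is.finite(prefilterCutoff))
        pairPrefilter(f1, x1, f2, x2, prefilterCutoff) else
        list(decided = FALSE, connDecided = FALSE)
      if (pf$decided) {
        out <- rbind(out, data.frame(i = i, j = j, ENB = NA_real_,
                                     EB = NA_real_, clash = pf$clash,
                                     conn = pf$conn))
      } else {
        # a bonded pair with unbondable attachment geometry needs only ENB
        pend[[length(pend) + 1L]] <- list(i = i, j = j,
          bonded = bondedPair[fi, fj] && !isTRUE(pf$connDecided))
      }
    }
  }

  if (mode == "energy" && length(pend)) {
    # one monomer energy per placement, evaluated once
    used <- sort(unique(unlist(lapply(pend, function(p) c(p$i, p$j)))))
    monoSDF <- lapply(used, function(i) {
      f <- frs[[tb$fragment[i]]]
      .rawSDF(f@compound@atoms$elem, placements@coords[[i]],
              f@compound@bonds$a1, f@compound@bonds$a2,
              f@compound@bonds$order)
    })
    sysSDF <- list(); sysKind <- character(0)
    for (p in pend) {
      f1 <- frs[[tb$fragment[p$i]]]; f2 <- frs[[tb$fragment[p$j]]]
      x1 <- placements@coords[[p$i]]; x2 <- placements@coords[[p$j]]
      sysSDF[[length(sysSDF) + 1L]] <- .dimerSDF(f1, x1, f2, x2)
      sysKind <- c(sysKind, "nb")
      if (p$bonded) {
        att <- f1@attachments[f1@attachments$partner == f2@id, ][1, ]
        sysSDF[[length(sysSDF) + 1L]] <- .mergedSDF(f1, x1, f2, x2, att)
        sysKind <- c(sysKind, "b")
      }
    }
    energies <- .uffEnergies(c(monoSDF, sysSDF))
    mono <- energies[seq_along(monoSDF)]
    names(mono) <- as.character(used)
    sysE <- energies[-seq_along(monoSDF)]
    cursor <- 1L
    rows <- lapply(pend, function(p) {
      base <- mono[[as.character(p$i)]] + mono[[as.character(p$j)]]
      enb <- sysE[cursor] - base
      cursor <<- cursor + 1L
      eb <- NA_real_
      if (p$bonded) {
        eb <- sysE[cursor] - base
        cursor <<- cursor + 1L
      }
      data.frame(i = p$i, j = p$j, ENB = enb, EB = eb,
                 bonded = p$bonded)
    })
    rows <- do.call(rbind, rows)
    rows <- binarizePairEnergies(rows, thE)
    rows$bonded <- NULL
    out <- rbind(out, rows)
  }

  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pair-term table to TSV
#'
#' @param terms data.frame from [pairTerms()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePairTermsTSV <- function(terms, file) {
  utils::write.table(terms, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
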