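# Pose reconstruction: merge the selected fragment placements into one
# compound pose, score it by redocking RMSD against a reference, and
# optionally relax it with a generic force-field minimization.

#' Assemble a compound pose from a valid solution
#'
#' Concatenates the selected placements' coordinates, deletes the two cap
#' hydrogens at every inter-fragment bond and adds the bond between the
#' attachment heavy atoms.  Coordinates are not moved: any distortion left
#' by the combinatorial selection stays in place (removal is delegated to
#' [minimizePose()]).
#'
#' @param x binary selection vector (one placement per fragment), e.g. a
#'   row of a [SolutionPool-class].
#' @param placements the [PlacementSet-class] the solution refers to.
#' @return a [ReconstructedPose-class]; heavy atoms are ordered by parent
#'   atom index, so the pose aligns atom-by-atom with the parent compound.
#' @export
assemblePose <- function(x, placements) {
  tb <- placements@table
  if (length(x) != nrow(tb)) stop("selection vector has wrong length")
  if (!all(x %in% c(0, 1))) stop("selection vector must be binary")
  sel <- which(x == 1)
  nf <- length(placements@fragmentation@fragments)
  selFrag <- tb$fragment[sel]
  if (length(sel) != nf || !setequal(selFrag, seq_len(nf)))
    stop("invalid solution: exactly one placement per fragment required")
  byFrag <- sel[order(selFrag)]
  coordsList <- lapply(byFrag, function(i) placements@coords[[i]])
  joined <- joinFragments(placements@fragmentation, coordsList)
  new("ReconstructedPose", compound = joined$compound,
      parentAtom = joined$parentAtom,
      placements = as.integer(tb$id[byFrag]))
}

# heavy-atom coordinate/element views of a pose or compound
.heavyView <- function(obj) {
  cmp <- if (is(obj, "ReconstructedPose")) obj@compound else obj
  if (is.null(cmp@coords)) stop("3D coordinates required for RMSD")
  hv <- .heavyIdx(cmp)
  list(compound = cmp, idx = hv, xyz = cmp@coords[hv, , drop = FALSE])
}

#' Redocking RMSD between a pose and a reference structure
#'
#' Heavy-atom RMSD without superposition: both structures are taken in the
#' common (protein) frame, the standard redocking convention.  With
#' `symmetry = TRUE` (default) the RMSD is minimized over all graph
#' automorphisms consistent with elements and bond orders, so chemically
#' equivalent atoms (e.g. the fluorines of a CF3 group or the two rings of
#' benzene) do not inflate the value.
#'
#' @param pose a [ReconstructedPose-class] or [Compound-class] with
#'   coordinates.
#' @param reference a [Compound-class] with coordinates and the same
#'   molecular graph.
#' @param symmetry minimize over graph automorphisms (default TRUE).
#' @return list with `rmsd` (Angstrom), `mapping` (pose heavy atom ->
#'   reference heavy atom) and `symmetryCorrected`.
#' @export
computeRMSD <- function(pose, reference, symmetry = TRUE) {
  a <- .heavyView(pose)
  b <- .heavyView(reference)
  if (length(a$idx) != length(b$idx))
    stop("pose and reference have different heavy-atom counts")
  maps <- .allIsomorphisms(a$compound, b$compound)
  if (!length(maps))
    stop("pose and reference do not share the same molecular graph")
  rmsdFor <- function(mp) {
    d <- a$xyz - b$xyz[mp, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }
  if (symmetry) {
    vals <- vapply(maps, rmsdFor, numeric(1))
    best <- which.min(vals)
    list(rmsd = vals[best], mapping = maps[[best]],
         symmetryCorrected = TRUE)
  } else {
    idMap <- seq_along(a$idx)
    useId <- any(vapply(maps, function(mp) identical(mp, idMap), logical(1)))
    mp <- if (useId) idMap else maps[[1]]
    list(rmsd = rmsdFor(mp), mapping = mp, symmetryCorrected = FALSE)
  }
}

#' Relax a reconstructed pose by force-field minimization
#'
#' Steepest-descent minimization of the compound's internal energy with
#' OpenBabel (UFF by default), removing the structural distortion left by
#' assembly (stretched inter-fragment bonds, clashes).  The minimization is
#' ligand-only: the protein environment is not part of the energy model
#' (the protein enters the workflow only through the placement scores).
#'
#' @param pose a [ReconstructedPose-class] or [Compound-class] with
#'   coordinates.
#' @param steps maximum minimization steps (default 500).
#' @param forcefield OpenBabel force-field name (default "UFF").
#' @return the input object with minimized coordinates.
#' @export
minimizePose <- function(pose, steps = 500L, forcefield = "UFF") {
  cmp <- if (is(pose, "ReconstructedPose")) pose@compound else pose
  if (is.null(cmp@coords)) stop("3D coordinates required")
  .obCheck()
  f <- .tempSDF(cmp)
  on.exit(unlink(f))
  out <- suppressWarnings(system2("obminimize",
    c("-n", as.character(steps), "-ff", forcefield, "-osdf", f),
    stdout = TRUE, stderr = FALSE))
  tmp <- tempfile(fileext = ".sdf")
  writeLines(out, tmp)
  on.exit(unlink(tmp), add = TRUE)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  ab <- ChemmineR::atomblock(sdfset[[1]])
  if (nrow(ab) != nrow(cmp@atoms))
    stop("minimization changed the atom count; force-field setup failed")
  newXyz <- unname(ab[, 1:3, drop = FALSE])
  if (is(pose, "ReconstructedPose")) {
    pose@compound@coords <- newXyz
    pose
  } else {
    cmp@coords <- newXyz
    cmp
  }
}

#' Hamiltonian-vs-RMSD table for a solution pool (funnel data)
#'
#' For every valid solution in the pool, assembles the pose and computes
#' its redocking RMSD to the reference.  The scatter of H against RMSD is
#' the funnel plot used to judge the Hamiltonian design: a well-designed
#' objective gives low RMSD at low H.
#'
#' @param pool a [SolutionPool-class] (typically post-filtered).
#' @param placements the [PlacementSet-class].
#' @param reference a [Compound-class] with coordinates.
#' @param symmetry passed to [computeRMSD()].
#' @return data.frame with columns `H` and `rmsd`, one row per valid
#'   solution.
#' @export
funnelTable <- function(pool, placements, reference, symmetry = TRUE) {
  keep <- which(pool@info$valid)
  rows <- lapply(keep, function(r) {
    pose <- assemblePose(pool@X[r, ], placements)
    data.frame(H = pool@info$H[r],
               rmsd = computeRMSD(pose, reference, symmetry)$rmsd)
  })
  if (!length(rows))
    return(data.frame(H = numeric(0), rmsd = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write reconstructed poses to a multi-record SDF
#'
#' @param poses list of [ReconstructedPose-class] objects.
#' @param file output path.
#' @param info optional data.frame of per-pose properties (e.g. H, rank,
#'   rmsd) written into the SD data block.
#' @return the path, invisibly.
#' @export
writePosesSDF <- function(poses, file, info = NULL) {
  cmps <- lapply(poses, function(p) p@compound)
  dbs <- NULL
  if (!is.null(info)) {
    dbs <- lapply(seq_len(nrow(info)), function(i) {
      v <- vapply(info[i, , drop = FALSE], function(col)
        as.character(col), character(1))
      names(v) <- names(info)
      v
    })
  }
  .writeCompoundsSDF(cmps, file, names = sprintf("pose_%d", seq_along(poses)),
                     datablocks = dbs)
}
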