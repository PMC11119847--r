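# Candidate fragment placements: subregion grid, pose ingestion with score
# filtering and per-subregion caps, and cross-subregion RMSD deduplication.

#' Construct a docking region
#'
#' @param center numeric length-3 box center (Angstrom).
#' @param edge box edge length (Angstrom).
#' @param cell subregion cell edge length (Angstrom, default 2).
#' @return a [DockingRegion-class].
#' @examples
#' dockingRegion(c(16.61, -7.03, 14.45), 14)   # the grid used for ALDR/2HV5
#' @export
dockingRegion <- function(center, edge, cell = 2) {
  obj <- new("DockingRegion", center = as.numeric(center),
             edge = as.numeric(edge), cell = as.numeric(cell))
  validObject(obj)
  obj
}

#' Enumerate the subregions tiling a docking region
#'
#' The cubic box is tiled by (edge/cell)^3 cubic cells.  Cells are anchored
#' at the box corner (center - edge/2 on each axis) and half-open, so every
#' point of the box maps to exactly one cell.
#'
#' @param region a [DockingRegion-class]; the box edge must be an integer
#'   multiple of the cell edge.
#' @return data.frame with 0-based integer indices `ix`, `iy`, `iz`
#'   (lexicographic order) and cell centers `cx`, `cy`, `cz` (Angstrom).
#' @examples
#' nrow(enumerateSubregions(dockingRegion(c(0, 0, 0), 14, 2)))  # 343
#' @export
enumerateSubregions <- function(region) {
  validObject(region)
  k <- region@edge / region@cell
  if (abs(k - round(k)) > 1e-9)
    stop("box edge must be an integer multiple of the cell edge")
  k <- as.integer(round(k))
  idx <- seq_len(k) - 1L
  grid <- expand.grid(iz = idx, iy = idx, ix = idx)[, 3:1]
  corner <- region@center - region@edge / 2
  data.frame(ix = grid$ix, iy = grid$iy, iz = grid$iz,
             cx = corner[1] + (grid$ix + 0.5) * region@cell,
             cy = corner[2] + (grid$iy + 0.5) * region@cell,
             cz = corner[3] + (grid$iz + 0.5) * region@cell)
}

# subregion index triple of a point, or NULL if outside the box
.subregionOf <- function(region, p) {
  corner <- region@center - region@edge / 2
  rel <- (p - corner) / region@cell
  k <- round(region@edge / region@cell)
  i <- floor(rel + 1e-12)
  if (any(i < 0) || any(i >= k)) return(NULL)
  as.integer(i)
}

.heavyCentroid <- function(fragment, xyz) {
  hv <- which(fragment@compound@atoms$elem != "H" &
              !is.na(fragment@atomMap))
  colMeans(xyz[hv, , drop = FALSE])
}

.newPlacementSet <- function(tb, coords, fragmentation) {
  if (nrow(tb)) {
    rownames(tb) <- NULL
    tb$id <- seq_len(nrow(tb))
  }
  obj <- new("PlacementSet", table = tb, coords = coords,
             fragmentation = fragmentation)
  validObject(obj)
  obj
}

.emptyPlacementTable <- function() {
  data.frame(id = integer(0), fragment = integer(0), score = numeric(0),
             subregion = character(0), cx = numeric(0), cy = numeric(0),
             cz = numeric(0), stringsAsFactors = FALSE)
}

#' Ingest externally docked fragment poses
#'
#' Reads a multi-record SDF of fragment poses (or an equivalent list), keeps
#' only poses with a negative binding-free-energy score, assigns each pose
#' to the subregion containing its heavy-atom centroid (poses outside the
#' box are dropped with a warning), and keeps per fragment per subregion at
#' most `perSubregionCap` best-scoring poses.
#'
#' @param poses path to a multi-record SDF whose records carry the
#'   properties `fragment_id` and `score`, or a list of entries
#'   `list(fragment=, score=, coords=)`.
#' @param fragmentation the [FragmentationResult-class] the poses refer to.
#' @param region a [DockingRegion-class].
#' @param perSubregionCap best poses kept per fragment per subregion
#'   (default 20).
#' @param scoreThreshold poses with `score >= scoreThreshold` are dropped
#'   (default 0 kcal/mol).
#' @return a [PlacementSet-class].
#' @export
ingestPoses <- function(poses, fragmentation, region,
                        perSubregionCap = 20L, scoreThreshold = 0) {
  entries <- if (is.character(poses)) {
    .readPoseSDF(poses, fragmentation)
  } else poses

  nf <- length(fragmentation@fragments)
  tb <- .emptyPlacementTable()
  coords <- list()
  nOutside <- 0L
  for (e in entries) {
    if (is.null(e$fragment) || is.na(e$fragment))
      stop("pose does not name its fragment (property 'fragment_id')")
    if (e$fragment < 1L || e$fragment > nf)
      stop("pose references unknown fragment id ", e$fragment)
    if (is.null(e$score) || is.na(e$score))
      stop("pose is missing its numeric 'score' property")
    if (e$score >= scoreThreshold) next
    frag <- fragmentation@fragments[[e$fragment]]
    if (nrow(e$coords) != nrow(frag@compound@atoms))
      stop("pose atom count does not match fragment ", e$fragment)
    ctr <- .heavyCentroid(frag, e$coords)
    sub <- if (!is.null(e$subregion)) e$subregion else
      .subregionOf(region, ctr)
    if (is.null(sub)) { nOutside <- nOutside + 1L; next }
    tb <- rbind(tb, data.frame(
      id = 0L, fragment = as.integer(e$fragment), score = e$score,
      subregion = paste(sub, collapse = ","),
      cx = ctr[1], cy = ctr[2], cz = ctr[3], stringsAsFactors = FALSE))
    coords[[length(coords) + 1L]] <- e$coords
  }
  if (nOutside > 0)
    warning(nOutside, " pose(s) with centroid outside the docking box dropped")

  if (nrow(tb)) {
    keep <- unlist(lapply(split(seq_len(nrow(tb)),
                                list(tb$fragment, tb$subregion), drop = TRUE),
                          function(idx) {
      idx[order(tb$score[idx])][seq_len(min(length(idx), perSubregionCap))]
    }))
    keep <- sort(keep)
    tb <- tb[keep, , drop = FALSE]
    coords <- coords[keep]
    # stable order: fragment, then score
    o <- order(tb$fragment, tb$score)
    tb <- tb[o, , drop = FALSE]
    coords <- coords[o]
  }
  .newPlacementSet(tb, coords, fragmentation)
}

# read a multi-record pose SDF (properties fragment_id, score; optional
# subregion "ix,iy,iz")
.readPoseSDF <- function(file, fragmentation) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(file))
  lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    db <- ChemmineR::datablock(sdf)
    fid <- suppressWarnings(as.integer(db[["fragment_id"]]))
    sc <- if ("score" %in% names(db))
      suppressWarnings(as.numeric(db[["score"]])) else NA_real_
    sub <- NULL
    if ("subregion" %in% names(db) && !is.na(db[["subregion"]]) &&
        grepl("^-?[0-9]", db[["subregion"]]))
      sub <- as.integer(strsplit(db[["subregion"]], ",")[[1]])
    ab <- ChemmineR::atomblock(sdf)
    list(fragment = fid, score = sc, subregion = sub,
         coords = unname(ab[, 1:3, drop = FALSE]))
  })
}

# heavy-atom identity-mapping RMSD between two poses of the same fragment
# (cap hydrogens excluded)
.poseRMSD <- function(fragment, xyz1, xyz2) {
  hv <- which(fragment@compound@atoms$elem != "H")
  d <- xyz1[hv, , drop = FALSE] - xyz2[hv, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Deduplicate similar placements across subregions
#'
#' Within each fragment, placements are visited best score first and a
#' placement is accepted only when its heavy-atom identity-mapping RMSD to
#' every already accepted placement is at least `rmsdThreshold`.  Each
#' cluster of mutually similar poses thus keeps its best-scoring
#' representative, and the global best placement of every fragment always
#' survives.
#'
#' @param placements a [PlacementSet-class].
#' @param rmsdThreshold minimum pairwise RMSD between survivors (Angstrom,
#'   default 1.0).
#' @return the deduplicated [PlacementSet-class].
#' @export
dedupPlacements <- function(placements, rmsdThreshold = 1.0) {
  if (rmsdThreshold <= 0) stop("rmsdThreshold must be positive")
  tb <- placements@table
  if (!nrow(tb)) return(placements)
  keep <- logical(nrow(tb))
  for (k in unique(tb$fragment)) {
    frag <- placements@fragmentation@fragments[[k]]
    idx <- which(tb$fragment == k)
    idx <- idx[order(tb$score[idx], idx)]
    accepted <- integer(0)
    for (i in idx) {
      ok <- TRUE
      for (a in accepted) {
        if (.poseRMSD(frag, placements@coords[[i]],
                      placements@coords[[a]]) < rmsdThreshold) {
          ok <- FALSE
          break
        }
      }
      if (ok) { accepted <- c(accepted, i); keep[i] <- TRUE }
    }
  }
  tb2 <- tb[keep, , drop = FALSE]
  o <- order(tb2$fragment, tb2$score)
  .newPlacementSet(tb2[o, , drop = FALSE],
                   placements@coords[keep][o], placements@fragmentation)
}

#' Build a placement set directly from pose entries
#'
#' Convenience constructor used by the synthetic generator and by tests:
#' no score filtering or capping is applied.
#'
#' @param entries list of `list(fragment=, score=, coords=, subregion=)`.
#' @param fragmentation a [FragmentationResult-class].
#' @return a [PlacementSet-class].
#' @export
placementSet <- function(entries, fragmentation) {
  tb <- .emptyPlacementTable()
  coords <- list()
  for (e in entries) {
    frag <- fragmentation@fragments[[e$fragment]]
    ctr <- .heavyCentroid(frag, e$coords)
    tb <- rbind(tb, data.frame(
      id = 0L, fragment = as.integer(e$fragment), score = e$score,
      subregion = if (!is.null(e$subregion))
        paste(e$subregion, collapse = ",") else NA_character_,
      cx = ctr[1], cy = ctr[2], cz = ctr[3], stringsAsFactors = FALSE))
    coords[[length(coords) + 1L]] <- e$coords
  }
  .newPlacementSet(tb, coords, fragmentation)
}

#' Write a placement table to TSV
#'
#' @param placements a [PlacementSet-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePlacementsTSV <- function(placements, file) {
  utils::write.table(placements@table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write placements as a multi-record SDF with score properties
#'
#' @param placements a [PlacementSet-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePlacementsSDF <- function(placements, file) {
  tb <- placements@table
  cmps <- lapply(seq_len(nrow(tb)), function(i) {
    frag <- placements@fragmentation@fragments[[tb$fragment[i]]]
    cmp <- frag@compound
    cmp@coords <- placements@coords[[i]]
    cmp@id <- sprintf("placement_%d", tb$id[i])
    cmp
  })
  dbs <- lapply(seq_len(nrow(tb)), function(i) {
    c(fragment_id = as.character(tb$fragment[i]),
      score = sprintf("%.6f", tb$score[i]),
      subregion = as.character(tb$subregion[i]))
  })
  .writeCompoundsSDF(cmps, file, names = sprintf("placement_%d", tb$id),
                     datablocks = dbs)
}
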