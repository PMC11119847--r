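# Molecule ingestion and SDF plumbing.
#
# SDF/MOL records are parsed with ChemmineR; SMILES parsing, canonical
# SMILES generation and force-field calls go through the OpenBabel
# command-line tools (obabel / obenergy / obminimize), which are a
# SystemRequirement of the package.

.obCheck <- local({
  done <- FALSE
  function() {
    if (!done) {
      if (Sys.which("obabel") == "")
        stop("OpenBabel 'obabel' not found on PATH", call. = FALSE)
      done <<- TRUE
    }
    invisible(TRUE)
  }
})

.obabel <- function(args, stdin_text = NULL) {
  .obCheck()
  out <- suppressWarnings(system2("obabel", args,
                                  stdout = TRUE, stderr = FALSE,
                                  input = stdin_text))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("obabel failed (exit ", status, ")", call. = FALSE)
  out
}

# ring bonds = bonds that are not bridges of the molecular graph
.ringBonds <- function(n, a1, a2) {
  if (length(a1) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(a1, a2), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  res <- rep(TRUE, length(a1))
  res[as.integer(br)] <- FALSE
  res
}

# V2000 old-style charge codes (field 6 of the atom line)
.chargeFromCode <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Build a Compound from a ChemmineR SDF object
.sdfToCompound <- function(sdf, id = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  if (all(abs(coords) < 1e-12)) coords <- NULL
  charge <- if (ncol(ab) >= 6) .chargeFromCode(ab[, 6]) else rep(0L, nrow(ab))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  if (nrow(bb) > 0) {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord,
                        ring = .ringBonds(nrow(ab), a1, a2))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), ring = logical(0))
  }
  new("Compound",
      atoms = data.frame(elem = elem, charge = charge,
                         stringsAsFactors = FALSE),
      bonds = bonds, coords = coords, id = as.character(id))
}

# Build a ChemmineR SDF object from atom/bond tables (for write.SDF and
# for feeding OpenBabel)
.compoundToSDF <- function(compound, name = compound@id,
                           datablock = character(0)) {
  n <- nrow(compound@atoms)
  m <- nrow(compound@bonds)
  xyz <- if (is.null(compound@coords)) matrix(0, n, 3) else compound@coords
  # 4 decimals keep the fixed-width V2000 atom block aligned
  ab <- cbind(round(xyz, 4), matrix(0L, n, 12))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(compound@atoms$elem, seq_len(n), sep = "_")
  if (m > 0) {
    bb <- cbind(compound@bonds$a1, compound@bonds$a2, compound@bonds$order,
                matrix(0L, m, 4))
  } else {
    bb <- matrix(integer(0), 0, 7)
  }
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- as.character(seq_len(m))
  header <- c(Molecule_Name = name, Source = "  quboDock          3D",
              Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, m))
  new("SDF", header = header, atomblock = ab, bondblock = bb,
      datablock = datablock)
}

.writeCompoundsSDF <- function(compounds, file, names = NULL,
                               datablocks = NULL) {
  if (is.null(names)) names <- vapply(compounds, function(x) x@id, character(1))
  sdfs <- lapply(seq_along(compounds), function(i) {
    db <- if (is.null(datablocks)) character(0) else datablocks[[i]]
    .compoundToSDF(compounds[[i]], name = names[i], datablock = db)
  })
  sdfset <- new("SDFset", SDF = sdfs, ID = names)
  ChemmineR::write.SDF(sdfset, file = file, cid = TRUE)
  invisible(file)
}

.tempSDF <- function(compound) {
  f <- tempfile(fileext = ".sdf")
  .writeCompoundsSDF(list(compound), f)
  f
}

#' Load a compound from a SMILES string or an SDF/MOL file
#'
#' SMILES strings are parsed with OpenBabel (no 3D coordinates are
#' generated); SDF/MOL records are read with ChemmineR and keep their 3D
#' coordinates when present.
#'
#' @param source a SMILES string, or a path to an SDF/MOL file.
#' @param id identifier for the compound; defaults to the SMILES string or
#'   the molecule name in the file.
#' @param record which record of a multi-record SDF to load (default 1).
#' @return a [Compound-class].
#' @examples
#' cmp <- loadCompound("CCO")
#' atomTable(cmp)
#' @export
loadCompound <- function(source, id = NULL, record = 1L) {
  if (length(source) != 1L || !is.character(source))
    stop("'source' must be a single SMILES string or file path")
  if (file.exists(source)) {
    txt <- readLines(source, warn = FALSE)
    if (!any(grepl("^\\${4}", txt))) txt <- c(txt, "$$$$")  # bare MOL file
    tmp <- tempfile(fileext = ".sdf")
    writeLines(txt, tmp)
    on.exit(unlink(tmp))
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    if (length(sdfset) < record) stop("record ", record, " not found in file")
    sdf <- sdfset[[record]]
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    cmp <- .sdfToCompound(sdf, id = if (!is.null(id)) id else
                          if (nzchar(nm)) nm else basename(source))
  } else {
    out <- tryCatch(.obabel(c(shQuote(paste0("-:", source)), "-osdf"),
                            stdin_text = NULL),
                    error = function(e) character(0))
    if (!length(out) || !any(grepl("V2000", out)))
      stop("cannot parse '", source, "' as SMILES or locate it as a file")
    tmp <- tempfile(fileext = ".sdf")
    writeLines(out, tmp)
    on.exit(unlink(tmp))
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    cmp <- .sdfToCompound(sdfset[[1]], id = if (!is.null(id)) id else source)
  }
  validObject(cmp)
  cmp
}

#' Canonical SMILES of a compound
#'
#' Generated with OpenBabel; explicit (cap) hydrogens are folded into the
#' implicit-hydrogen canonical form, so capped fragments compare equal to
#' their conventional SMILES.
#'
#' @param compound a [Compound-class].
#' @return a single character string.
#' @export
canonicalSmiles <- function(compound) {
  f <- .tempSDF(compound)
  on.exit(unlink(f))
  out <- .obabel(c(f, "-ocan"))
  out <- out[nzchar(out)]
  if (!length(out)) stop("canonical SMILES generation failed")
  strsplit(trimws(out[1]), "[ \t]")[[1]][1]
}

# heavy-atom indices of a compound
.heavyIdx <- function(compound) which(compound@atoms$elem != "H")

# igraph of a compound, optionally heavy atoms only, with element colors
.moleculeGraph <- function(compound, heavyOnly = TRUE) {
  keep <- if (heavyOnly) .heavyIdx(compound) else seq_len(nrow(compound@atoms))
  remap <- match(seq_len(nrow(compound@atoms)), keep)
  b <- compound@bonds
  sel <- b$a1 %in% keep & b$a2 %in% keep
  g <- igraph::make_empty_graph(length(keep), directed = FALSE)
  if (any(sel))
    g <- igraph::add_edges(g, rbind(remap[b$a1[sel]], remap[b$a2[sel]]))
  elems <- compound@atoms$elem[keep]
  igraph::V(g)$elem <- elems
  igraph::V(g)$color <- as.integer(factor(elems,
    levels = sort(unique(elems))))
  # ring bonds share one edge color: Kekule structures of the same
  # aromatic ring must compare equal (a 60-degree benzene rotation is an
  # automorphism even though it swaps alternating single/double bonds)
  if (any(sel)) igraph::E(g)$order <- ifelse(b$ring[sel], 0L, b$order[sel])
  g
}

# graph isomorphism of two compounds (heavy atoms, element + bond-order
# colors); returns TRUE/FALSE
.isIsomorphic <- function(c1, c2) {
  g1 <- .moleculeGraph(c1); g2 <- .moleculeGraph(c2)
  if (igraph::vcount(g1) != igraph::vcount(g2)) return(FALSE)
  lev <- sort(unique(c(igraph::V(g1)$elem, igraph::V(g2)$elem)))
  col1 <- as.integer(factor(igraph::V(g1)$elem, levels = lev))
  col2 <- as.integer(factor(igraph::V(g2)$elem, levels = lev))
  e1 <- if (igraph::ecount(g1)) igraph::E(g1)$order else integer(0)
  e2 <- if (igraph::ecount(g2)) igraph::E(g2)$order else integer(0)
  igraph::is_isomorphic_to(g1, g2, method = "vf2",
                           vertex.color1 = col1, vertex.color2 = col2,
                           edge.color1 = e1, edge.color2 = e2)
}

# all isomorphisms g1 -> g2 as a list of index vectors
.allIsomorphisms <- function(c1, c2) {
  g1 <- .moleculeGraph(c1); g2 <- .moleculeGraph(c2)
  lev <- sort(unique(c(igraph::V(g1)$elem, igraph::V(g2)$elem)))
  col1 <- as.integer(factor(igraph::V(g1)$elem, levels = lev))
  col2 <- as.integer(factor(igraph::V(g2)$elem, levels = lev))
  e1 <- if (igraph::ecount(g1)) igraph::E(g1)$order else integer(0)
  e2 <- if (igraph::ecount(g2)) igraph::E(g2)$order else integer(0)
  maps <- igraph::graph.get.isomorphisms.vf2(g1, g2,
    vertex.color1 = col1, vertex.color2 = col2,
    edge.color1 = e1, edge.color2 = e2)
  lapply(maps, as.integer)
}

#' Write a compound to an SDF file
#'
#' @param compound a [Compound-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCompoundSDF <- function(compound, file) {
  .writeCompoundsSDF(list(compound), file)
}

#' Write fragments to a multi-record SDF file
#'
#' Each record carries the properties `fragment_id`, `parent_id`,
#' `capped_smiles` and `attachments` (a JSON-encoded attachment table), so
#' fragment files are self-describing.
#'
#' @param fragmentation a [FragmentationResult-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeFragmentsSDF <- function(fragmentation, file) {
  frs <- fragmentation@fragments
  dbs <- lapply(frs, function(f) {
    c(fragment_id = as.character(f@id),
      parent_id = fragmentation@parent@id,
      capped_smiles = f@smiles,
      attachments = as.character(
        jsonlite::toJSON(f@attachments, dataframe = "columns")))
  })
  .writeCompoundsSDF(lapply(frs, function(f) f@compound), file,
                     names = sprintf("fragment_%d", vapply(frs, function(f)
                       f@id, integer(1))),
                     datablocks = dbs)
}
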