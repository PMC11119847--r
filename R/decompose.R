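# Compound decomposition into rigid, hydrogen-capped fragments.
#
# A compound is cut at rotatable bonds so that every fragment has no
# internal degree of freedom.  Candidate cut bonds are single, non-ring
# bonds whose two heavy end atoms each have at least two heavy neighbours.
# Candidates are cut greedily in a fixed priority order (bonds between two
# non-ring atoms first, then bonds involving a heteroatom end), and a cut
# is skipped when an earlier cut has already reduced one end to a single
# heavy neighbour.  The greedy order keeps linker methylenes attached to
# the adjacent ring system instead of isolating them as bare carbons, and
# reproduces the conventional fragmentation of drug-like compounds (e.g. a
# CF3 group caps to FC(F)F, a carboxyl to OC=O, and an N-CH2-heteroaryl
# linker stays with the heteroaryl ring as a methyl).

.CAP_BOND_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34, P = 1.42)

.capLength <- function(elem) {
  if (elem %in% names(.CAP_BOND_LENGTH)) .CAP_BOND_LENGTH[[elem]] else 1.0
}

#' Decompose a compound into rigid fragments
#'
#' Cuts the compound at rotatable acyclic single bonds, caps each open
#' valence with one hydrogen, and records reciprocal attachment records so
#' the parent can be re-formed.  A compound with no cuttable bond yields a
#' single fragment.
#'
#' @param compound a [Compound-class].
#' @return a [FragmentationResult-class].
#' @examples
#' fr <- decompose(loadCompound("CCCC"))
#' fragmentSmiles(fr)   # two ethane fragments
#' @export
decompose <- function(compound) {
  validObject(compound)
  atoms <- compound@atoms
  bonds <- compound@bonds
  n <- nrow(atoms)
  heavy <- atoms$elem != "H"

  heavyDeg <- integer(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (heavy[a1] && heavy[a2]) {
        heavyDeg[a1] <- heavyDeg[a1] + 1L
        heavyDeg[a2] <- heavyDeg[a2] + 1L
      }
    }
  }

  cand <- which(bonds$order == 1L & !bonds$ring &
                heavy[bonds$a1] & heavy[bonds$a2] &
                heavyDeg[bonds$a1] >= 2L & heavyDeg[bonds$a2] >= 2L)

  # greedy priority: fewer ring-member ends first, heteroatom ends first
  if (length(cand)) {
    inRing <- logical(n)
    if (any(bonds$ring)) {
      r <- bonds[bonds$ring, ]
      inRing[unique(c(r$a1, r$a2))] <- TRUE
    }
    ringEnds <- inRing[bonds$a1[cand]] + inRing[bonds$a2[cand]]
    hetEnds <- (!atoms$elem[bonds$a1[cand]] %in% c("C", "H")) +
               (!atoms$elem[bonds$a2[cand]] %in% c("C", "H"))
    cand <- cand[order(ringEnds, -hetEnds, cand)]
  }

  deg <- heavyDeg
  cut <- integer(0)
  for (b in cand) {
    a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
    if (deg[a1] >= 2L && deg[a2] >= 2L) {
      cut <- c(cut, b)
      deg[a1] <- deg[a1] - 1L
      deg[a2] <- deg[a2] - 1L
    }
  }

  # connected components of the graph after cutting (H atoms follow their
  # heavy neighbour automatically: H bonds are never cut)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  keepBonds <- setdiff(seq_len(nrow(bonds)), cut)
  if (length(keepBonds))
    g <- igraph::add_edges(g, rbind(bonds$a1[keepBonds], bonds$a2[keepBonds]))
  comp <- igraph::components(g)$membership

  # deterministic fragment order: by smallest parent atom index
  comps <- split(seq_len(n), comp)
  comps <- comps[order(vapply(comps, min, integer(1)))]
  nf <- length(comps)
  fragOf <- integer(n)
  for (k in seq_len(nf)) fragOf[comps[[k]]] <- k

  hasCoords <- !is.null(compound@coords)

  # per-fragment scaffolding (atoms in parent order, caps appended)
  fragAtoms   <- lapply(comps, function(idx) idx)   # parent indices
  fragCaps    <- vector("list", nf)                 # one row per cut bond end
  interBonds  <- data.frame(f1 = integer(0), f2 = integer(0),
                            a1 = integer(0), a2 = integer(0))

  for (b in cut) {
    a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
    f1 <- fragOf[a1]; f2 <- fragOf[a2]
    lo <- min(f1, f2); hi <- max(f1, f2)
    if (f1 > f2) { tmp <- a1; a1 <- a2; a2 <- tmp }
    interBonds <- rbind(interBonds,
                        data.frame(f1 = lo, f2 = hi, a1 = a1, a2 = a2))
    fragCaps[[lo]] <- rbind(fragCaps[[lo]],
      data.frame(heavyParent = a1, partnerFrag = hi, partnerParent = a2))
    fragCaps[[hi]] <- rbind(fragCaps[[hi]],
      data.frame(heavyParent = a2, partnerFrag = lo, partnerParent = a1))
  }

  buildFragment <- function(k) {
    idx <- fragAtoms[[k]]
    caps <- fragCaps[[k]]
    ncap <- if (is.null(caps)) 0L else nrow(caps)
    local <- match(seq_len(n), idx)       # parent -> fragment-local
    na <- length(idx)

    elem <- c(atoms$elem[idx], rep("H", ncap))
    charge <- c(atoms$charge[idx], rep(0L, ncap))

    sel <- bonds$a1 %in% idx & bonds$a2 %in% idx
    fb <- data.frame(a1 = local[bonds$a1[sel]], a2 = local[bonds$a2[sel]],
                     order = bonds$order[sel], ring = bonds$ring[sel])
    if (ncap > 0)
      fb <- rbind(fb, data.frame(a1 = local[caps$heavyParent],
                                 a2 = na + seq_len(ncap),
                                 order = 1L, ring = FALSE))

    xyz <- NULL
    if (hasCoords) {
      xyz <- compound@coords[idx, , drop = FALSE]
      if (ncap > 0) {
        capXyz <- t(vapply(seq_len(ncap), function(ci) {
          p <- compound@coords[caps$heavyParent[ci], ]
          q <- compound@coords[caps$partnerParent[ci], ]
          v <- q - p
          nv <- sqrt(sum(v^2))
          if (nv < 1e-9) v <- c(1, 0, 0) else v <- v / nv
          p + v * .capLength(atoms$elem[caps$heavyParent[ci]])
        }, numeric(3)))
        xyz <- rbind(xyz, capXyz)
      }
    }

    cmp <- new("Compound",
               atoms = data.frame(elem = elem, charge = charge,
                                  stringsAsFactors = FALSE),
               bonds = fb, coords = xyz,
               id = sprintf("%s|fragment_%d", compound@id, k))
    validObject(cmp)

    att <- if (ncap > 0) {
      data.frame(heavy = local[caps$heavyParent],
                 cap = na + seq_len(ncap),
                 partner = caps$partnerFrag,
                 partnerHeavy = NA_integer_,       # filled below
                 partnerParent = caps$partnerParent)
    } else {
      data.frame(heavy = integer(0), cap = integer(0), partner = integer(0),
                 partnerHeavy = integer(0), partnerParent = integer(0))
    }
    list(compound = cmp, atomMap = c(idx, rep(NA_integer_, ncap)), att = att)
  }

  built <- lapply(seq_len(nf), buildFragment)

  # resolve partner fragment-local heavy indices
  for (k in seq_len(nf)) {
    att <- built[[k]]$att
    if (nrow(att)) {
      att$partnerHeavy <- vapply(seq_len(nrow(att)), function(r) {
        pm <- built[[att$partner[r]]]$atomMap
        match(att$partnerParent[r], pm)
      }, integer(1))
      built[[k]]$att <- att
    }
  }

  frs <- lapply(seq_len(nf), function(k) {
    att <- built[[k]]$att
    att$partnerParent <- NULL
    f <- new("Fragment", id = k, compound = built[[k]]$compound,
             smiles = canonicalSmiles(built[[k]]$compound),
             atomMap = built[[k]]$atomMap, attachments = att)
    validObject(f)
    f
  })

  res <- new("FragmentationResult", fragments = frs,
             bonds = interBonds, parent = compound)
  validObject(res)
  res
}

#' Re-join fragments into a single molecule
#'
#' Removes the cap hydrogens at every inter-fragment bond, concatenates the
#' fragments and adds the bonds between the attachment heavy atoms.  Used
#' both by pose assembly and as a structural round-trip check.  Atoms in
#' the result are ordered by their parent atom index, so the output aligns
#' atom-by-atom with the parent compound.
#'
#' @param fragmentation a [FragmentationResult-class].
#' @param coordsList optional list with one coordinate matrix per fragment
#'   (fragment atom order).  When NULL, fragment coordinates (if any) are
#'   used.
#' @return a list with elements `compound` (the joined [Compound-class])
#'   and `parentAtom` (joined atom index -> parent atom index).
#' @export
joinFragments <- function(fragmentation, coordsList = NULL) {
  frs <- fragmentation@fragments
  nf <- length(frs)
  if (!is.null(coordsList) && length(coordsList) != nf)
    stop("coordsList must have one matrix per fragment")

  # caps consumed by formed bonds
  consumed <- lapply(frs, function(f) f@attachments$cap)

  elem <- character(0); charge <- integer(0); parentAtom <- integer(0)
  xyz <- NULL
  globalIdx <- vector("list", nf)   # fragment-local -> joined index
  anyCoords <- !is.null(coordsList) ||
    all(vapply(frs, function(f) !is.null(f@compound@coords), logical(1)))

  for (k in seq_len(nf)) {
    f <- frs[[k]]
    na <- nrow(f@compound@atoms)
    keep <- setdiff(seq_len(na), consumed[[k]])
    gi <- rep(NA_integer_, na)
    gi[keep] <- length(elem) + seq_along(keep)
    globalIdx[[k]] <- gi
    elem <- c(elem, f@compound@atoms$elem[keep])
    charge <- c(charge, f@compound@atoms$charge[keep])
    parentAtom <- c(parentAtom, f@atomMap[keep])
    if (anyCoords) {
      cm <- if (!is.null(coordsList)) coordsList[[k]] else f@compound@coords
      if (is.null(cm)) { anyCoords <- FALSE; xyz <- NULL }
      else xyz <- rbind(xyz, cm[keep, , drop = FALSE])
    }
  }

  # intra-fragment bonds (minus cap bonds at consumed caps)
  a1 <- integer(0); a2 <- integer(0); ord <- integer(0); ring <- logical(0)
  for (k in seq_len(nf)) {
    f <- frs[[k]]
    gi <- globalIdx[[k]]
    fb <- f@compound@bonds
    sel <- !is.na(gi[fb$a1]) & !is.na(gi[fb$a2])
    a1 <- c(a1, gi[fb$a1[sel]]); a2 <- c(a2, gi[fb$a2[sel]])
    ord <- c(ord, fb$order[sel]); ring <- c(ring, fb$ring[sel])
  }
  # formed inter-fragment bonds (always single: only single bonds are cut)
  ib <- fragmentation@bonds
  for (r in seq_len(nrow(ib))) {
    l1 <- match(ib$a1[r], frs[[ib$f1[r]]]@atomMap)
    l2 <- match(ib$a2[r], frs[[ib$f2[r]]]@atomMap)
    a1 <- c(a1, globalIdx[[ib$f1[r]]][l1])
    a2 <- c(a2, globalIdx[[ib$f2[r]]][l2])
    ord <- c(ord, 1L); ring <- c(ring, FALSE)
  }

  # order atoms by parent index for atom-wise comparability
  o <- order(parentAtom, na.last = TRUE)
  rank <- match(seq_along(o), o)
  cmp <- new("Compound",
             atoms = data.frame(elem = elem[o], charge = charge[o],
                                stringsAsFactors = FALSE),
             bonds = data.frame(a1 = pmin(rank[a1], rank[a2]),
                                a2 = pmax(rank[a1], rank[a2]),
                                order = ord, ring = ring),
             coords = if (anyCoords) xyz[o, , drop = FALSE] else NULL,
             id = sprintf("%s|joined", fragmentation@parent@id))
  validObject(cmp)
  list(compound = cmp, parentAtom = parentAtom[o])
}
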