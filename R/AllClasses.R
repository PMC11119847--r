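#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Compound: a small molecule as an annotated molecular graph
#'
#' Holds the atom table (element, formal charge), the bond table (atom index
#' pair, bond order, ring membership) and, optionally, one 3D position per
#' atom in Angstrom.  The molecular graph must be connected.
#'
#' @slot atoms data.frame with columns `elem` (character) and `charge`
#'   (integer), one row per atom (explicit hydrogens included when present
#'   in the source record).
#' @slot bonds data.frame with columns `a1`, `a2` (integer atom indices),
#'   `order` (integer bond order, 1/2/3) and `ring` (logical).
#' @slot coords numeric matrix (n x 3, Angstrom) or NULL.
#' @slot id character identifier (name or SMILES).
#' @exportClass Compound
setClass("Compound",
  representation(
    atoms  = "data.frame",
    bonds  = "data.frame",
    coords = "matrixOrNULL",
    id     = "character"
  )
)

setValidity("Compound", function(object) {
  msg <- character(0)
  n <- nrow(object@atoms)
  if (n == 0L) msg <- c(msg, "compound has no atoms")
  if (!all(c("elem", "charge") %in% names(object@atoms)))
    msg <- c(msg, "atoms table needs columns 'elem', 'charge'")
  if (nrow(object@bonds) > 0 &&
      !all(c("a1", "a2", "order", "ring") %in% names(object@bonds)))
    msg <- c(msg, "bonds table needs columns 'a1', 'a2', 'order', 'ring'")
  if (nrow(object@bonds) > 0) {
    idx <- c(object@bonds$a1, object@bonds$a2)
    if (any(idx < 1L | idx > n)) msg <- c(msg, "bond atom index out of range")
  }
  if (!is.null(object@coords)) {
    if (nrow(object@coords) != n || ncol(object@coords) != 3L)
      msg <- c(msg, "coords must be an n x 3 matrix")
  }
  if (n > 1L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(object@bonds) > 0)
      g <- igraph::add_edges(g, rbind(object@bonds$a1, object@bonds$a2))
    if (igraph::components(g)$no != 1L)
      msg <- c(msg, "molecular graph is not connected")
  }
  if (length(msg)) msg else TRUE
})

#' Fragment: a rigid, hydrogen-capped substructure of a parent compound
#'
#' A fragment is obtained by cutting the parent at rotatable bonds; every
#' open valence created by a cut is capped with exactly one hydrogen.  The
#' `atomMap` links fragment atoms back to parent atoms (NA for cap
#' hydrogens), and `attachments` records, per cut bond, which heavy atom and
#' cap belong to this fragment and which fragment/atom sits on the other
#' side in the parent.
#'
#' @slot id integer fragment id (1-based, within a FragmentationResult).
#' @slot compound the capped fragment as a [Compound-class].
#' @slot smiles canonical SMILES of the capped fragment (identity key).
#' @slot atomMap integer vector, fragment atom index -> parent atom index
#'   (NA for cap hydrogens).
#' @slot attachments data.frame with columns `heavy` (this fragment's heavy
#'   atom, fragment-local index), `cap` (this fragment's cap hydrogen,
#'   fragment-local index), `partner` (partner fragment id) and
#'   `partnerHeavy` (partner's heavy atom, partner-fragment-local index).
#' @exportClass Fragment
setClass("Fragment",
  representation(
    id          = "integer",
    compound    = "Compound",
    smiles      = "character",
    atomMap     = "integer",
    attachments = "data.frame"
  )
)

setValidity("Fragment", function(object) {
  msg <- character(0)
  n <- nrow(object@compound@atoms)
  if (length(object@atomMap) != n)
    msg <- c(msg, "atomMap length must equal fragment atom count")
  att <- object@attachments
  if (nrow(att) > 0) {
    if (!all(c("heavy", "cap", "partner", "partnerHeavy") %in% names(att)))
      msg <- c(msg, "attachments need columns heavy, cap, partner, partnerHeavy")
    else {
      if (any(att$heavy < 1L | att$heavy > n) || any(att$cap < 1L | att$cap > n))
        msg <- c(msg, "attachment atom index out of range")
      if (any(!is.na(object@atomMap[att$cap])))
        msg <- c(msg, "attachment caps must be cap hydrogens (atomMap NA)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FragmentationResult: a compound partitioned into rigid fragments
#'
#' @slot fragments list of [Fragment-class] objects; `fragments[[k]]` has
#'   id `k`.
#' @slot bonds data.frame of inter-fragment bonds with columns `f1`, `f2`
#'   (fragment ids) and `a1`, `a2` (parent atom indices of the cut bond).
#' @slot parent the parent [Compound-class].
#' @exportClass FragmentationResult
setClass("FragmentationResult",
  representation(
    fragments = "list",
    bonds     = "data.frame",
    parent    = "Compound"
  )
)

setValidity("FragmentationResult", function(object) {
  msg <- character(0)
  heavyParent <- which(object@parent@atoms$elem != "H")
  mapped <- unlist(lapply(object@fragments, function(f) {
    m <- f@atomMap[!is.na(f@atomMap)]
    m[object@parent@atoms$elem[m] != "H"]
  }))
  if (!setequal(mapped, heavyParent) || anyDuplicated(mapped))
    msg <- c(msg, "fragments must partition the parent's heavy atoms")
  if (length(msg)) msg else TRUE
})

#' DockingRegion: the cubic docking box and its subregion grid
#'
#' @slot center numeric length-3, box center (Angstrom).
#' @slot edge numeric, box edge length (Angstrom).
#' @slot cell numeric, subregion cell edge length (Angstrom).
#' @exportClass DockingRegion
setClass("DockingRegion",
  representation(center = "numeric", edge = "numeric", cell = "numeric")
)

setValidity("DockingRegion", function(object) {
  msg <- character(0)
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (object@edge <= 0 || object@cell <= 0)
    msg <- c(msg, "edge and cell lengths must be positive")
  if (object@cell > object@edge)
    msg <- c(msg, "cell edge must not exceed box edge")
  if (length(msg)) msg else TRUE
})

#' PlacementSet: candidate fragment placements mapped to QUBO variables
#'
#' Row order of `table` is the QUBO variable order; ids are dense 1..n.
#'
#' @slot table data.frame with columns `id`, `fragment`, `score` (kcal/mol),
#'   `subregion` (character "ix,iy,iz" or NA) and `cx`, `cy`, `cz`
#'   (heavy-atom centroid).
#' @slot coords list of numeric matrices (one per placement, all atoms of
#'   the capped fragment in fragment atom order).
#' @slot fragmentation the [FragmentationResult-class] the placements
#'   refer to.
#' @exportClass PlacementSet
setClass("PlacementSet",
  representation(
    table         = "data.frame",
    coords        = "list",
    fragmentation = "FragmentationResult"
  )
)

setValidity("PlacementSet", function(object) {
  msg <- character(0)
  tb <- object@table
  if (nrow(tb) != length(object@coords))
    msg <- c(msg, "one coordinate matrix per placement required")
  if (nrow(tb) > 0) {
    if (!identical(tb$id, seq_len(nrow(tb))))
      msg <- c(msg, "placement ids must be dense 1..n in table order")
    nf <- length(object@fragmentation@fragments)
    if (any(tb$fragment < 1L | tb$fragment > nf))
      msg <- c(msg, "placement references unknown fragment")
    for (i in seq_len(nrow(tb))) {
      na <- nrow(object@fragmentation@fragments[[tb$fragment[i]]]@compound@atoms)
      if (nrow(object@coords[[i]]) != na) {
        msg <- c(msg, "placement atom count does not match its fragment")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' QUBOProblem: the four-term docking Hamiltonian as an explicit QUBO
#'
#' Stores both the reduced quadratic form (linear terms `h`, quadratic terms
#' `J` over unordered pairs i < j, constant `offset`) and the raw
#' ingredients (scores, binarized pair terms, fragment groups, weights) so
#' the Hamiltonian can be evaluated through two independent routes.
#'
#' @slot n integer, number of binary variables.
#' @slot h numeric length-n linear coefficients.
#' @slot J data.frame with columns `i`, `j` (i < j) and `value`.
#' @slot offset numeric constant.
#' @slot dG numeric length-n binding-free-energy scores (kcal/mol).
#' @slot terms data.frame of binarized pair terms (`i`, `j`, `clash`,
#'   `conn`).
#' @slot groups list mapping fragment id -> integer vector of its variable
#'   ids (S_k); may contain empty groups.
#' @slot weights named numeric (A, B, C, D).
#' @slot map data.frame mapping variable id -> placement id and fragment id.
#' @exportClass QUBOProblem
setClass("QUBOProblem",
  representation(
    n       = "integer",
    h       = "numeric",
    J       = "data.frame",
    offset  = "numeric",
    dG      = "numeric",
    terms   = "data.frame",
    groups  = "list",
    weights = "numeric",
    map     = "data.frame"
  )
)

setValidity("QUBOProblem", function(object) {
  msg <- character(0)
  if (length(object@h) != object@n) msg <- c(msg, "length(h) must equal n")
  if (length(object@dG) != object@n) msg <- c(msg, "length(dG) must equal n")
  if (!identical(sort(names(object@weights)), c("A", "B", "C", "D")))
    msg <- c(msg, "weights must be named A, B, C, D")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (nrow(object@J) > 0 && any(object@J$i >= object@J$j))
    msg <- c(msg, "J must be stored over unordered pairs i < j")
  gv <- unlist(object@groups)
  if (length(gv) && (anyDuplicated(gv) || !setequal(gv, seq_len(object@n))))
    msg <- c(msg, "fragment groups must partition the variables")
  if (length(msg)) msg else TRUE
})

#' SolutionPool: distinct solutions of a QUBO instance, sorted by energy
#'
#' @slot X integer 0/1 matrix, one solution per row (n columns).
#' @slot info data.frame with one row per solution: `H`, `H1`..`H4`,
#'   `valid` (exactly one placement per fragment), `solver`, `restart`.
#' @exportClass SolutionPool
setClass("SolutionPool",
  representation(X = "matrix", info = "data.frame")
)

setValidity("SolutionPool", function(object) {
  msg <- character(0)
  if (nrow(object@X) != nrow(object@info))
    msg <- c(msg, "one info row per solution required")
  if (length(object@X) && !all(object@X %in% c(0L, 1L)))
    msg <- c(msg, "solutions must be binary")
  if (nrow(object@X) > 1 && anyDuplicated(apply(object@X, 1, paste, collapse = "")))
    msg <- c(msg, "solution pool must not contain duplicate vectors")
  if (is.unsorted(object@info$H)) msg <- c(msg, "pool must be sorted by H")
  if (length(msg)) msg else TRUE
})

#' ReconstructedPose: a docked compound pose assembled from fragment placements
#'
#' @slot compound the assembled molecule with 3D coordinates (heavy atoms in
#'   parent atom order; caps at formed bonds removed).
#' @slot parentAtom integer vector, pose atom index -> parent atom index
#'   (NA for retained cap hydrogens at uncut positions).
#' @slot placements integer vector, placement id used per fragment.
#' @exportClass ReconstructedPose
setClass("ReconstructedPose",
  representation(
    compound   = "Compound",
    parentAtom = "integer",
    placements = "integer"
  )
)

#' SyntheticInstance: a planted-solution docking instance
#'
#' @slot compound the synthetic parent compound with native 3D coordinates.
#' @slot fragmentation its [FragmentationResult-class].
#' @slot placements [PlacementSet-class] (planted poses plus decoys).
#' @slot terms data.frame of binarized pair terms.
#' @slot planted integer 0/1 vector: the planted selection.
#' @slot config list, the generator configuration used.
#' @exportClass SyntheticInstance
setClass("SyntheticInstance",
  representation(
    compound      = "Compound",
    fragmentation = "FragmentationResult",
    placements    = "PlacementSet",
    terms         = "data.frame",
    planted       = "integer",
    config        = "list"
  )
)
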