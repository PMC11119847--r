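#' Accessors for quboDock classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname accessors
#' @export
setGeneric("coordMatrix", function(x) standardGeneric("coordMatrix"))
#' @rdname accessors
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("interFragmentBonds", function(x) standardGeneric("interFragmentBonds"))
#' @rdname accessors
#' @export
setGeneric("parentCompound", function(x) standardGeneric("parentCompound"))
#' @rdname accessors
#' @export
setGeneric("fragmentSmiles", function(x) standardGeneric("fragmentSmiles"))
#' @rdname accessors
#' @export
setGeneric("attachmentRecords", function(x) standardGeneric("attachmentRecords"))
#' @rdname accessors
#' @export
setGeneric("placementTable", function(x) standardGeneric("placementTable"))
#' @rdname accessors
#' @export
setGeneric("placementCoords", function(x, i) standardGeneric("placementCoords"))
#' @rdname accessors
#' @export
setGeneric("fragmentGroups", function(x) standardGeneric("fragmentGroups"))
#' @rdname accessors
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))
#' @rdname accessors
#' @export
setGeneric("linearTerms", function(x) standardGeneric("linearTerms"))
#' @rdname accessors
#' @export
setGeneric("quadraticTerms", function(x) standardGeneric("quadraticTerms"))
#' @rdname accessors
#' @export
setGeneric("quboOffset", function(x) standardGeneric("quboOffset"))
#' @rdname accessors
#' @export
setGeneric("quboWeights", function(x) standardGeneric("quboWeights"))
#' @rdname accessors
#' @export
setGeneric("solutionMatrix", function(x) standardGeneric("solutionMatrix"))
#' @rdname accessors
#' @export
setGeneric("solutionInfo", function(x) standardGeneric("solutionInfo"))

# ---- methods -----------------------------------------------------------

#' @rdname accessors
setMethod("atomTable", "Compound", function(x) x@atoms)
#' @rdname accessors
setMethod("bondTable", "Compound", function(x) x@bonds)
#' @rdname accessors
setMethod("coordMatrix", "Compound", function(x) x@coords)
#' @rdname accessors
setMethod("compoundId", "Compound", function(x) x@id)

#' @rdname accessors
setMethod("fragments", "FragmentationResult", function(x) x@fragments)
#' @rdname accessors
setMethod("interFragmentBonds", "FragmentationResult", function(x) x@bonds)
#' @rdname accessors
setMethod("parentCompound", "FragmentationResult", function(x) x@parent)
#' @rdname accessors
setMethod("fragmentSmiles", "FragmentationResult",
  function(x) vapply(x@fragments, function(f) f@smiles, character(1)))
#' @rdname accessors
setMethod("fragmentSmiles", "Fragment", function(x) x@smiles)
#' @rdname accessors
setMethod("attachmentRecords", "Fragment", function(x) x@attachments)

#' @rdname accessors
setMethod("placementTable", "PlacementSet", function(x) x@table)
#' @rdname accessors
setMethod("placementCoords", "PlacementSet", function(x, i) x@coords[[i]])
#' @rdname accessors
setMethod("fragments", "PlacementSet", function(x) x@fragmentation@fragments)

#' @rdname accessors
setMethod("fragmentGroups", "PlacementSet", function(x) {
  nf <- length(x@fragmentation@fragments)
  lapply(seq_len(nf), function(k) which(x@table$fragment == k))
})

#' @rdname accessors
setMethod("nVariables", "QUBOProblem", function(x) x@n)
#' @rdname accessors
setMethod("linearTerms", "QUBOProblem", function(x) x@h)
#' @rdname accessors
setMethod("quadraticTerms", "QUBOProblem", function(x) x@J)
#' @rdname accessors
setMethod("quboOffset", "QUBOProblem", function(x) x@offset)
#' @rdname accessors
setMethod("quboWeights", "QUBOProblem", function(x) x@weights)
#' @rdname accessors
setMethod("fragmentGroups", "QUBOProblem", function(x) x@groups)

#' @rdname accessors
setMethod("solutionMatrix", "SolutionPool", function(x) x@X)
#' @rdname accessors
setMethod("solutionInfo", "SolutionPool", function(x) x@info)

#' @rdname accessors
setMethod("coordMatrix", "ReconstructedPose", function(x) x@compound@coords)

# ---- show methods ------------------------------------------------------

setMethod("show", "Compound", function(object) {
  heavy <- sum(object@atoms$elem != "H")
  cat("Compound \"", object@id, "\": ", nrow(object@atoms), " atoms (",
      heavy, " heavy), ", nrow(object@bonds), " bonds, ",
      if (is.null(object@coords)) "no coordinates" else "3D coordinates",
      "\n", sep = "")
})

setMethod("show", "Fragment", function(object) {
  cat("Fragment ", object@id, ": ", object@smiles, " (",
      nrow(object@compound@atoms), " atoms, ",
      nrow(object@attachments), " attachment(s))\n", sep = "")
})

setMethod("show", "FragmentationResult", function(object) {
  cat("FragmentationResult: ", length(object@fragments),
      " fragment(s) of \"", object@parent@id, "\"\n", sep = "")
  for (f in object@fragments)
    cat("  [", f@id, "] ", f@smiles, "\n", sep = "")
  if (nrow(object@bonds))
    cat("  inter-fragment bonds: ",
        paste(object@bonds$f1, object@bonds$f2, sep = "-", collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "DockingRegion", function(object) {
  cat(sprintf("DockingRegion: center (%.2f, %.2f, %.2f) A, edge %.1f A, cell %.1f A\n",
              object@center[1], object@center[2], object@center[3],
              object@edge, object@cell))
})

setMethod("show", "PlacementSet", function(object) {
  cat("PlacementSet: ", nrow(object@table), " placement(s) over ",
      length(object@fragmentation@fragments), " fragment(s)\n", sep = "")
  if (nrow(object@table)) {
    byf <- table(object@table$fragment)
    cat("  per fragment: ", paste(names(byf), byf, sep = ":", collapse = " "),
        "\n  score range: [", sprintf("%.3f", min(object@table$score)), ", ",
        sprintf("%.3f", max(object@table$score)), "] kcal/mol\n", sep = "")
  }
})

setMethod("show", "QUBOProblem", function(object) {
  cat("QUBOProblem: ", object@n, " variable(s), ", nrow(object@J),
      " quadratic term(s), offset ", format(object@offset), "\n  weights: A=",
      object@weights["A"], " B=", object@weights["B"], " C=",
      object@weights["C"], " D=", object@weights["D"], "\n", sep = "")
})

setMethod("show", "SolutionPool", function(object) {
  cat("SolutionPool: ", nrow(object@X), " solution(s)", sep = "")
  if (nrow(object@X)) {
    cat(", best H = ", format(object@info$H[1]), ", valid: ",
        sum(object@info$valid), "/", nrow(object@X), sep = "")
  }
  cat("\n")
})

setMethod("show", "ReconstructedPose", function(object) {
  cat("ReconstructedPose from placements [",
      paste(object@placements, collapse = ", "), "]: ",
      nrow(object@compound@atoms), " atoms\n", sep = "")
})

setMethod("show", "SyntheticInstance", function(object) {
  cat("SyntheticInstance: K=", length(object@fragmentation@fragments),
      " fragments, ", nrow(object@placements@table),
      " placements, pair-term mode \"", object@config$mode, "\"\n", sep = "")
})
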